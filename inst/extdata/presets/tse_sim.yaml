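# Low-resolution TSE simulation protocol
name: tse_sim
builder: tse
phantom: t2_plane
fov: 0.25
matrix_n: 32
n_slices: 1
slice_thickness: 0.005
tr: 4.5
te: 0.010
etl: 4
center_echo: 2
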