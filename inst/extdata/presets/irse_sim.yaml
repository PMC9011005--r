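# Low-resolution IRSE simulation protocol
name: irse_sim
builder: irse
phantom: t1_plane
fov: 0.25
matrix_n: 32
n_slices: 1
slice_thickness: 0.005
tr: 4.5
te: 0.010
ti: 0.200
etl: 1
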