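# 23-echo multi-echo TSE T2 mapping protocol (TE = 7..161 ms, 7 ms apart)
name: tse_t2map
builder: multiecho
phantom: t2_plane
fov: 0.25
matrix_n: 128
n_slices: 1
slice_thickness: 0.006
tr: 4.5
echo_spacing: 0.007
n_echoes: 23
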