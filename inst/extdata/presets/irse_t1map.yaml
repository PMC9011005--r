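# 10-TI inversion-recovery T1 mapping protocol
name: irse_t1map
builder: t1map
phantom: t1_plane
fov: 0.25
matrix_n: 128
n_slices: 1
slice_thickness: 0.006
tr: 4.5
te: 0.010
etl: 1
ti_list: [0.050, 0.075, 0.100, 0.125, 0.150, 0.250, 1.000, 1.500, 2.000, 3.000]
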