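# Qualitative IRSE, ACR-style multi-slice protocol
name: irse_acr
builder: irse
phantom: grid
fov: 0.25
matrix_n: 256
n_slices: 11
slice_thickness: 0.005
tr: 2.0
te: 0.012
ti: 0.150
etl: 1
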