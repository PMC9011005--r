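# Qualitative TSE, ACR-style multi-slice protocol
name: tse_acr
builder: tse
phantom: grid
fov: 0.25
matrix_n: 256
n_slices: 11
slice_thickness: 0.005
tr: 3.0
te: 0.050
etl: 4
center_echo: 2
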