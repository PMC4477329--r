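# Synthetic stand-in mixing matrix for the five-component RGB phantom.
# Rows: components 1..5; columns: red, green, blue channel intensity.
# Constructed (not measured) so that the five spectral profiles are nearly
# parallel: mutual coherence 0.9995, average pairwise coherence 0.9956.
red,green,blue
0.771838291415617,0.643638847341849,0.707738569378733
0.0970440889322297,0.0850132812458399,0.0819703123769941
0.325948071712311,0.312982035647041,0.273114569211335
0.507202609753138,0.561956613551571,0.469575741215048
0.837631967748324,0.977684119890235,0.840065860923354
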