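# chromophore: beta-carotene (effective dermal contribution)
# value_kind: absorption coefficient, cm^-1
# provenance: synthetic approximation with the published band shape (blue-green
#   absorption peaking near 460 nm) scaled to a typical dermal carotenoid load;
#   linear interpolation between rows is intended
wavelength_nm	value
400	0.080
410	0.100
420	0.130
430	0.160
440	0.185
450	0.205
462	0.220
470	0.210
480	0.190
490	0.150
500	0.100
510	0.060
520	0.030
530	0.015
540	0.008
550	0.004
560	0.002
580	0.001
600	0.0005
650	0.0002
700	0.0001
800	0.0001
900	0.0001
1000	0.0001
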