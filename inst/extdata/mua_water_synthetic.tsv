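# chromophore: water
# value_kind: absorption coefficient, cm^-1
# provenance: synthetic approximation reconstructed from well-known anchor values of
#   published pure-water absorption compilations (visible minimum, 970 nm band);
#   linear interpolation between rows is intended
wavelength_nm	value
400	0.000066
420	0.000047
440	0.000065
450	0.000092
475	0.000114
500	0.000204
525	0.000320
550	0.000565
575	0.000935
600	0.002224
625	0.002800
650	0.003400
675	0.004400
700	0.006200
725	0.015500
750	0.026000
775	0.024000
800	0.020000
825	0.028000
850	0.043000
875	0.054000
900	0.068000
925	0.140000
950	0.300000
970	0.450000
985	0.420000
1000	0.360000
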