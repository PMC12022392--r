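# chromophore: fat (purified subcutaneous lipid)
# value_kind: absorption coefficient, cm^-1
# provenance: synthetic approximation reconstructed from well-known anchor values of
#   published purified-fat spectra (930 nm lipid band, weak visible absorption);
#   linear interpolation between rows is intended
wavelength_nm	value
400	0.200
425	0.150
450	0.120
475	0.100
500	0.090
525	0.075
550	0.060
575	0.050
600	0.040
625	0.035
650	0.030
675	0.027
700	0.025
725	0.030
750	0.035
775	0.040
800	0.045
825	0.052
850	0.060
875	0.110
900	0.300
915	0.600
925	0.950
930	1.150
940	0.950
950	0.650
960	0.450
980	0.330
1000	0.280
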