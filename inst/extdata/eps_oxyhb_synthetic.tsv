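# chromophore: oxyhemoglobin (HbO2)
# value_kind: molar extinction coefficient, L mol^-1 cm^-1 (per 64500 g/mol tetramer)
# provenance: synthetic approximation reconstructed from well-known anchor values of
#   the standard compiled HbO2 spectrum (Soret band ~414 nm, Q bands 540/576 nm);
#   linear interpolation between rows is intended
wavelength_nm	value
400	266000
405	330000
410	467000
414	523000
418	480000
422	330000
426	220000
430	140000
435	90000
440	62000
450	45000
460	33000
470	27000
480	24000
490	23000
500	20900
510	20000
520	24500
530	39900
540	53200
544	53800
548	49500
552	41000
556	32500
560	27000
564	28500
568	39000
572	50500
576	55500
580	50000
584	39000
588	26000
592	15000
596	7500
600	3200
610	1500
620	950
630	650
640	440
650	368
660	320
670	290
680	278
690	280
700	290
710	310
720	340
730	390
740	446
750	518
760	586
770	650
780	710
790	765
800	816
820	920
840	1022
860	1092
880	1154
900	1198
920	1220
940	1250
960	1280
980	1240
1000	1190
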