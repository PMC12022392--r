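# chromophore: deoxyhemoglobin (Hb)
# value_kind: molar extinction coefficient, L mol^-1 cm^-1 (per 64500 g/mol tetramer)
# provenance: synthetic approximation reconstructed from well-known anchor values of
#   the standard compiled Hb spectrum (Soret band ~430 nm, single Q band ~555 nm,
#   NIR bump ~760 nm); linear interpolation between rows is intended
wavelength_nm	value
400	223000
405	250000
410	280000
415	310000
420	350000
425	450000
430	530000
435	460000
440	350000
445	200000
450	103000
460	62000
470	42000
480	31000
490	26000
500	20900
510	19000
520	21000
530	30000
540	46600
545	50500
550	52500
555	53400
560	52500
565	49000
570	45000
576	39000
580	35500
586	29000
590	25500
600	14700
610	9400
620	6510
630	5150
640	4350
650	3750
660	3230
670	2800
680	2410
690	2050
700	1790
710	1580
720	1460
730	1300
740	1320
750	1520
760	1670
770	1480
780	1350
790	1050
800	762
820	720
840	692
860	700
880	726
900	745
920	755
940	750
960	735
980	725
1000	690
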