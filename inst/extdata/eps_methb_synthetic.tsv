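# chromophore: methemoglobin (MetHb, aquomet form, neutral pH)
# value_kind: molar extinction coefficient, L mol^-1 cm^-1 (per 64500 g/mol tetramer)
# provenance: synthetic approximation reconstructed from well-known anchor values of
#   published MetHb spectra (Soret ~406 nm, broad band ~500 nm, characteristic
#   630 nm band); linear interpolation between rows is intended
wavelength_nm	value
400	560000
406	680000
412	520000
420	320000
430	170000
440	120000
450	80000
460	56000
470	45000
480	40200
490	37200
500	36200
505	36400
510	36000
520	33600
530	31200
540	29000
550	24400
560	22000
570	19600
580	18000
590	15600
600	14400
610	12800
620	14000
628	14900
632	14800
640	13200
650	9600
660	8000
670	5600
680	4800
690	4000
700	3600
720	3000
740	2600
760	2500
780	2600
800	2800
820	3000
840	3200
860	3400
880	3700
900	4000
920	4200
940	4400
960	4500
980	4700
1000	4800
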