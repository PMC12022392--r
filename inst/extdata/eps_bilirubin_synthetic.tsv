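# chromophore: bilirubin
# value_kind: molar extinction coefficient, L mol^-1 cm^-1
# provenance: synthetic approximation reconstructed from well-known anchor values of
#   published bilirubin spectra (single visible band peaking near 455-460 nm);
#   linear interpolation between rows is intended
wavelength_nm	value
400	25000
410	29000
420	38000
430	44000
440	50000
450	54500
455	55000
460	54500
470	49000
480	42000
490	32000
500	22000
510	14000
520	8000
530	4200
540	2000
550	900
560	400
570	170
580	80
590	30
600	10
650	2
700	1
800	1
900	1
1000	1
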