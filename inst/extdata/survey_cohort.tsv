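region	group	date_range	n_samples	n_positive	total_spectra	pooled_note	eurasian
Britain	Northern Europe	ca. 800 BCE to 1895 CE	33	11	128	FALSE	TRUE
Denmark	Northern Europe	ca. 3000-1500 BCE	2	0	0	FALSE	TRUE
Norway	Northern Europe	1100-1700 CE	5	1	43	TRUE	TRUE
Germany	Central Europe	ca. 3000 BCE to 1200 CE	9	0	0	FALSE	TRUE
Hungary	Central Europe	ca. 3000-1500 BCE	2	1	38	FALSE	TRUE
Italy	Central Europe	ca. 2700 BCE to 200 CE	17	4	11	FALSE	TRUE
Armenia	Northern Southwest Asia	ca. 2000-700 BCE	4	1	2	FALSE	TRUE
Russia	Northern Southwest Asia	ca. 3000-1500 BCE	2	1	8	FALSE	TRUE
St. Helena	Central West Africa	ca. 1840-1872 CE	18	0	0	FALSE	FALSE
Eastern Settlement	Greenland (Norse)	ca. 890-1230 CE	2	2	38	FALSE	FALSE
Western Settlement	Greenland (Norse)	ca. 1290-1430 CE	4	1	1	FALSE	FALSE
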