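# Reference per-site BEB posterior probabilities of positive selection for
# the opossum vWF A1/A2 fragment, as reported for the two foreground
# schemes (excluding / including the untested aquatic lineage).
# Sites are numbered by the Mus mature peptide; NA = reported below 0.50
# or not reported for that scheme.
ref_pos	residue	p_selected_exclude	p_selected_include	binding
533	L	0.80	0.71	FALSE
560	D	0.62	NA	FALSE
567	E	NA	0.75	FALSE
590	Q	0.99	1.00	FALSE
601	T	NA	0.85	FALSE
610	D	1.00	0.99	FALSE
622	T	0.54	NA	FALSE
625	Q	0.65	NA	FALSE
628	P	0.88	0.82	TRUE
631	A	0.95	0.89	FALSE
633	N	NA	0.98	FALSE
635	V	0.60	0.98	TRUE
636	R	0.74	0.91	TRUE
639	Q	NA	0.73	TRUE
642	K	0.71	0.50	FALSE
643	K	1.00	0.99	TRUE
647	I	0.84	0.69	FALSE
657	A	0.57	NA	FALSE
658	S	0.55	NA	FALSE
664	L	0.69	0.57	TRUE
668	Q	0.89	0.98	TRUE
669	A	0.84	0.77	FALSE
670	P	0.79	0.70	FALSE
674	A	1.00	0.99	FALSE
692	S	0.93	1.00	FALSE
694	L	NA	0.69	FALSE
705	T	0.83	0.69	FALSE
728	K	0.60	NA	FALSE
753	K	NA	0.95	FALSE
795	K	0.76	0.66	FALSE
838	P	NA	0.69	FALSE
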