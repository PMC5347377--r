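id	group	population	sex	age	total_snvs
MA-Depression-1	MDD	MA	Female	35	8348095
MA-Depression-2	MDD	MA	Female	30	7921961
MA-Depression-3	MDD	MA	Female	41	8037674
MA-Depression-4	MDD	MA	Female	32	8021058
MA-Depression-5	MDD	MA	Female	45	7839942
MA-Depression-6	MDD	MA	Female	38	7834986
MA-Depression-7	MDD	MA	Female	36	7935708
MA-Depression-8	MDD	MA	Female	59	7694178
MA-Depression-9	MDD	MA	Female	41	7778564
MA-Depression-10	MDD	MA	Female	31	8073958
MA-Control-1	Control	MA	Female	50	7879192
MA-Control-2	Control	MA	Female	45	6974138
MA-Control-3	Control	MA	Female	39	6911665
MA-Control-4	Control	MA	Female	29	7197066
MA-Control-5	Control	MA	Female	35	7487135
AU-Depression-1	MDD	AU	Male	44	3883255
AU-Depression-2	MDD	AU	Female	19	3938868
AU-Depression-3	MDD	AU	Female	19	3925906
AU-Depression-4	MDD	AU	Female	25	3933654
AU-Depression-5	MDD	AU	Female	18	3905386
AU-Control-1	Control	AU	Female	20	3898847
AU-Control-2	Control	AU	Male	18	3920681
AU-Control-3	Control	AU	Male	30	3861132
AU-Control-4	Control	AU	Female	18	3922531
AU-Control-5	Control	AU	Male	20	3820520
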