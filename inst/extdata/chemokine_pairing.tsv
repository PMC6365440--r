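ligand	receptor
Ccl2	Ccr2
Ccl3	Ccr1
Ccl3	Ccr5
Ccl4	Ccr5
Ccl5	Ccr1
Ccl5	Ccr3
Ccl5	Ccr5
Ccl6	Ccr1
Ccl7	Ccr1
Ccl7	Ccr2
Ccl7	Ccr3
Ccl8	Ccr8
Ccl9	Ccr1
Ccl11	Ccr3
Ccl12	Ccr2
Ccl17	Ccr4
Ccl19	Ccr7
Ccl20	Ccr6
Ccl21	Ccr7
Ccl22	Ccr4
Ccl24	Ccr3
Ccl25	Ccr9
Ccl27	Ccr10
Ccl28	Ccr3
Ccl28	Ccr10
Cxcl1	Cxcr2
Cxcl2	Cxcr2
Cxcl3	Cxcr2
Cxcl5	Cxcr2
Cxcl9	Cxcr3
Cxcl10	Cxcr3
Cxcl11	Cxcr3
Cxcl12	Cxcr4
Cxcl13	Cxcr5
Cxcl16	Cxcr6
Cx3cl1	Cx3cr1
Xcl1	Xcr1
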