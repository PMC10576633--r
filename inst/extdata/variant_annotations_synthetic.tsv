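variant_id	gene	protein_change	function_class
chr2:25234373:C/T	DNMT3A	p.R882H	missense
chr4:55599321:A/T	KIT	p.D816V	missense
chr13:28592642:C/A	FLT3	p.D835Y	missense
chr17:7577120:C/T	TP53	p.R273H	missense
chr2:209113112:G/A	IDH1	p.R132H	missense
chr15:90631934:C/T	IDH2	p.R140Q	missense
chr1:115258747:C/T	NRAS	p.G12D	missense
chr21:36252877:C/T	RUNX1	p.R201*	nonsense
chr1:1100:A/G	GENE_A	p.K10R	missense
chr1:1200:A/G	GENE_B	p.L25V	missense
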