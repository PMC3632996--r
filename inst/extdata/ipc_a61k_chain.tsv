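code	parent_code	level	definition	synonyms
A		1	Human necessities	
A61	A	2	Medical or veterinary science; Hygiene	
A61K	A61	3	Preparations for medical, dental or toilet purposes	
A61K 38/00	A61K	4	Medicinal preparations containing peptides	
A61K 38/16	A61K 38/00	5	Peptides having more than 20 amino acids; Gastrins; Somatostatins; Melanotropins; Derivatives thereof	
A61K 38/17	A61K 38/16	6	from animals; from humans	
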