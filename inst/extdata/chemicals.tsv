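name	abbreviation	cas	solvent	cv75	llna_category	hclat_judgment
2,4-Dinitrochlorobenzene	DNCB	97-00-7	DMSO		Extreme	p
1,4-Phenylendiamine	PPDA				Strong	p
Nickel sulfate	NiSO4				Moderate	p
2-Mercaptobenzothiazole	MBT				Moderate	p
R(+)-Limonene	LIM				Weak	p
Imidazolidinyl urea	IU				Weak	p
Isopropanol					non-sensitizer	n
Glycerol					non-sensitizer	n
4-Aminobenzoic acid					non-sensitizer	n
Potassium dichromate					Extreme	p
Benzoyl peroxide					Extreme	n
Cobalt chloride					Strong	p
4-Nitrobenzyl bromide					Strong	p
Maleic acid					Strong	p
2-Aminophenol					Strong	p
Lauryl gallate					Strong	p
Methyl methanesulfonate					Moderate	n
Citral					Moderate	p
Resorcinol					Moderate	p
Diethylenetriamine					Moderate	n
Cinnamaldehyde					Moderate	p
3-Propylidenephthalide					Moderate	p
Phenylacetaldehyde					Moderate	p
3-Dimethylamino propylamine					Moderate	p
1-Phenyl-1,2-propanedione					Moderate	p
Isoeugenol					Moderate	n
Oxalic acid anhydrous					Weak	p
Geraniol					Weak	p
1,2-Propanediol					non-sensitizer	n
4-Hydroxybenzoic acid					non-sensitizer	n
Sulfanilamide					non-sensitizer	n
Coumarin					non-sensitizer	n
4-Methoxyacetophenone					non-sensitizer	n
Ethyl benzoylacetate					non-sensitizer	n
1-Butanol					non-sensitizer	n
Saccharin					non-sensitizer	n
Sodium Sulfite					ND	p
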