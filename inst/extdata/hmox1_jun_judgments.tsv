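chemical	printed_call	printed_match
Potassium dichromate	non-sensitizer	Mismatch
Benzoyl peroxide	sensitizer	Match
Cobalt chloride	sensitizer	Match
4-Nitrobenzyl bromide	sensitizer	Match
Maleic acid	sensitizer	Match
2-Aminophenol	sensitizer	Match
Lauryl gallate	sensitizer	Match
Methyl methanesulfonate	sensitizer	Match
Citral	sensitizer	Match
Resorcinol	sensitizer	Match
Diethylenetriamine	sensitizer	Match
Cinnamaldehyde	sensitizer	Match
3-Propylidenephthalide	sensitizer	Match
Phenylacetaldehyde	sensitizer	Match
3-Dimethylamino propylamine	sensitizer	Match
1-Phenyl-1,2-propanedione	sensitizer	Match
Isoeugenol	sensitizer	Match
Oxalic acid anhydrous	sensitizer	Match
Geraniol	sensitizer	Match
1,2-Propanediol	non-sensitizer	Match
4-Hydroxybenzoic acid	non-sensitizer	Match
Sulfanilamide	non-sensitizer	Match
Coumarin	sensitizer	Mismatch
4-Methoxyacetophenone	non-sensitizer	Match
Ethyl benzoylacetate	sensitizer	Mismatch
1-Butanol	non-sensitizer	Match
Saccharin	sensitizer	Mismatch
Sodium Sulfite	sensitizer	-
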