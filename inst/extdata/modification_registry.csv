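name,formula,category,subcategory
Methylation,CH2,generic,none
Methoxylation,CH2O,generic,none
Hydroxylation,H2O,generic,none
Methyl ammonia,CH3NH2,generic,none
Acetylation,CH2CO,generic,none
Carboxylation,COO,generic,none
Sulfation,SO3,generic,none
Malonyl,C3H2O3,generic,none
Pentosylation,C5H8O4,generic,none
Deoxyhexosylation,C6H10O4,generic,none
Hexosylation,C6H10O5,generic,none
Putrescine,C4H12N2,specific,amine-conjugation
Cadaverine,C5H14N2,specific,amine-conjugation
Agmatine,C5H14N4,specific,amine-conjugation
Tyramine,C8H11NO,specific,amine-conjugation
Spermidine,C7H19N3,specific,amine-conjugation
Octopamine/dopamine,C8H11NO2,specific,amine-conjugation
Tryptamine,C10H12N2,specific,amine-conjugation
3-Methoxytyramine,C9H13NO2,specific,amine-conjugation
Noradrenaline,C8H11NO3,specific,amine-conjugation
Serotonin,C10H12N2O,specific,amine-conjugation
3'-Methoxyoctopamine,C9H13NO3,specific,amine-conjugation
5-Methoxytryptamine,C11H14N2O,specific,amine-conjugation
Spermine,C10H26N4,specific,amine-conjugation
Coumaryl,C9H6O2,specific,hydroxycinnamoyl-conjugation
Caffeoyl,C9H6O3,specific,hydroxycinnamoyl-conjugation
Feruloyl,C10H8O3,specific,hydroxycinnamoyl-conjugation
5-OH-Feruloyl,C10H8O4,specific,hydroxycinnamoyl-conjugation
Sinapyl,C11H10O4,specific,hydroxycinnamoyl-conjugation
Malate,C4H4O4,specific,acid-conjugation
Glyceric acid coupling,C3H4O3,specific,acid-conjugation
Phenylacetyl coupling,C8H6O,specific,acid-conjugation
Hydroxybenzoate,C7H4O2,specific,acid-conjugation
p-Hydroxybenzoylation,C7H6O2,specific,acid-conjugation
Tartarate,C4H4O5,specific,acid-conjugation
Dihydroxybenzoic acid coupling,C7H4O3,specific,acid-conjugation
Hydroxyadipic acid coupling,C6H8O4,specific,acid-conjugation
Vanillate,C8H6O3,specific,acid-conjugation
3-Dehydroshikimic acid coupling,C7H6O4,specific,acid-conjugation
Shikimic acid coupling,C7H8O4,specific,acid-conjugation
Quinic acid coupling,C7H10O5,specific,acid-conjugation
Syringate,C9H8O4,specific,acid-conjugation
Glycerol,C3H6O2,specific,alcohol-conjugation
Quinol,C6H4O,specific,alcohol-conjugation
Hydroxybenzyl alcohol,C7H6O,specific,alcohol-conjugation
Hydroxyquinol,C6H4O2,specific,alcohol-conjugation
Vanillyl alcohol,C8H8O2,specific,alcohol-conjugation
Coumaryl alcohol,C9H8O,specific,alcohol-conjugation
Caffeyl alcohol,C9H8O2,specific,alcohol-conjugation
Coniferyl alcohol,C10H10O2,specific,alcohol-conjugation
5-OH-Feruloyl alcohol,C10H10O3,specific,alcohol-conjugation
Sinapyl alcohol,C11H12O3,specific,alcohol-conjugation
Non-condensed vanillyl alcohol,C8H10O3,specific,alcohol-conjugation
Non-condensed coumaryl alcohol,C9H10O2,specific,alcohol-conjugation
Non-condensed caffeyl alcohol,C9H10O3,specific,alcohol-conjugation
Non-condensed coniferyl alcohol,C10H12O3,specific,alcohol-conjugation
Non-condensed 5-OH-feruloyl alcohol,C10H12O4,specific,alcohol-conjugation
Non-condensed sinapyl alcohol,C11H14O4,specific,alcohol-conjugation
Dimethoxyquinol,C8H8O3,specific,alcohol-conjugation
Syringyl alcohol,C9H10O3,specific,alcohol-conjugation
Isoprenylation,C5H8,specific,isoprenylation
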