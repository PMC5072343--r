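breed_category,breed,sex,genotype,n,uncertain
completely_polled,Australian Poll Merino,male,A/G,5,FALSE
completely_polled,Australian Poll Merino,male,G/G,93,FALSE
completely_polled,Australian Suffolk,male,A/G,1,FALSE
completely_polled,Australian Suffolk,male,G/G,108,FALSE
completely_polled,Comisana,female,A/G,5,FALSE
completely_polled,Comisana,female,G/G,93,FALSE
completely_polled,East Friesian Brown,male,G/G,15,FALSE
completely_polled,East Friesian Brown,female,A/G,1,FALSE
completely_polled,East Friesian Brown,female,G/G,23,FALSE
completely_polled,Irish Suffolk,male,A/G,1,FALSE
completely_polled,Irish Suffolk,male,G/G,38,FALSE
completely_polled,Irish Suffolk,female,G/G,16,FALSE
completely_polled,Rasa Aragonesa,male,A/G,1,FALSE
completely_polled,Rasa Aragonesa,male,G/G,3,FALSE
completely_polled,Rasa Aragonesa,female,A/G,1,FALSE
completely_polled,Rasa Aragonesa,female,G/G,17,FALSE
completely_polled,Scottish Texel,male,A/G,9,FALSE
completely_polled,Scottish Texel,male,G/G,31,FALSE
completely_polled,Scottish Texel,female,A/G,4,FALSE
completely_polled,Scottish Texel,female,G/G,36,FALSE
sex_dependent,Ethiopian Menz,male,A/G,1,FALSE
sex_dependent,Ethiopian Menz,male,G/G,17,FALSE
sex_dependent,Ethiopian Menz,female,A/G,3,FALSE
sex_dependent,Ethiopian Menz,female,G/G,13,FALSE
sex_dependent,Bangladeshi Garole,male,G/G,6,FALSE
sex_dependent,Bangladeshi Garole,female,G/G,18,FALSE
sex_dependent,Garut,male,G/G,8,FALSE
sex_dependent,Garut,female,G/G,14,FALSE
sex_dependent,Indian Garole,male,G/G,4,FALSE
sex_dependent,Indian Garole,female,G/G,22,FALSE
sex_dependent,Rambouillet,male,A/G,1,FALSE
sex_dependent,Rambouillet,male,G/G,75,FALSE
sex_dependent,Rambouillet,female,G/G,26,FALSE
completely_horned,Dorset Horn,male,A/A,3,FALSE
completely_horned,Dorset Horn,male,A/G,1,FALSE
completely_horned,Dorset Horn,female,A/A,12,FALSE
completely_horned,Dorset Horn,female,A/G,5,FALSE
completely_horned,Tibetan,male,A/A,19,FALSE
completely_horned,Tibetan,male,A/G,3,FALSE
completely_horned,Tibetan,female,A/A,14,FALSE
completely_horned,Tibetan,female,A/G,1,FALSE
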