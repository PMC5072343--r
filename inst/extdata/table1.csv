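breed_category,breed,sex,phenotype,genotype,n,uncertain
completely_polled,Barbados Black Belly,female,polled,anc/der,3,FALSE
completely_polled,Barbados Black Belly,unknown,polled,der/der,7,FALSE
completely_polled,Bentheimer,unknown,polled,der/der,4,FALSE
completely_polled,Charollais,unknown,polled,der/der,3,FALSE
completely_polled,Coburger,unknown,polled,der/der,18,FALSE
completely_polled,East Friesian (White),unknown,polled,der/der,20,FALSE
completely_polled,German Blackheaded Mutton,unknown,polled,der/der,20,FALSE
completely_polled,German Brown Mountain,unknown,polled,der/der,4,FALSE
completely_polled,German White Mountain,unknown,polled,der/der,20,FALSE
completely_polled,Ile de France,unknown,polled,der/der,3,FALSE
completely_polled,Merinolandschaf,unknown,polled,der/der,20,FALSE
completely_polled,Pomeranian Coarsewool,female,polled,anc/der,1,FALSE
completely_polled,Pomeranian Coarsewool,unknown,polled,der/der,18,FALSE
completely_polled,Rhoen,unknown,polled,der/der,20,FALSE
completely_polled,Rouge du Roussillon,unknown,polled,der/der,4,FALSE
completely_polled,Shropshire,unknown,polled,der/der,4,FALSE
completely_polled,Suffolk,unknown,polled,der/der,17,FALSE
completely_polled,Texel,unknown,polled,der/der,20,FALSE
completely_polled,White Polled Heidschnucke,unknown,polled,der/der,2,FALSE
completely_horned,Grey Horned Heidschnucke,unknown,horned,anc/anc,26,FALSE
completely_horned,Racka,unknown,horned,anc/anc,7,FALSE
completely_horned,Roux du Valais,unknown,horned,anc/anc,2,FALSE
completely_horned,Scottish Blackface,unknown,horned,anc/anc,18,FALSE
completely_horned,Soay,unknown,horned,anc/anc,9,FALSE
completely_horned,Valais Blacknose,unknown,horned,anc/anc,18,FALSE
completely_horned,White Horned Heidschnucke,unknown,horned,anc/anc,2,FALSE
completely_horned,Wiltshire Horn,unknown,horned,anc/anc,2,FALSE
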