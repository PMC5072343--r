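breed_category,cross,breed,phenotype,sex,genotype,n,uncertain
cross,single,East Friesian (White) x Grey Horned Heidschnucke,horned,male,anc/der,3,FALSE
cross,single,East Friesian (White) x Grey Horned Heidschnucke,polled,female,anc/der,3,FALSE
cross,single,Merinolandschaf x Grey Horned Heidschnucke,horned,male,anc/der,2,FALSE
cross,multi,Completely polled x completely horned breeds,horned,female,anc/anc,3,FALSE
cross,multi,Completely polled x completely horned breeds,polled,female,anc/der,4,FALSE
cross,multi,Completely polled x completely horned breeds,polled,female,der/der,2,FALSE
cross,multi,Completely polled x completely horned breeds,rudiments,female,anc/der,1,FALSE
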