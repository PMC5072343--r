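breed_category,breed,phenotype,sex,genotype,n,uncertain
variable,Bavarian Forest,horned,male,anc/anc,6,TRUE
variable,Bavarian Forest,horned,male,anc/der,3,TRUE
variable,Bavarian Forest,horned,female,anc/anc,1,TRUE
variable,Bavarian Forest,horned,female,anc/der,2,TRUE
variable,Bavarian Forest,rudiments,female,anc/der,1,TRUE
variable,Bavarian Forest,polled,male,der/der,1,TRUE
variable,Bavarian Forest,polled,female,anc/der,3,TRUE
variable,Bavarian Forest,polled,female,der/der,1,TRUE
variable,Bavarian Forest,scurred,male,anc/der,2,TRUE
variable,Bavarian Forest,scurred,female,anc/der,3,TRUE
variable,Alpines Steinschaf,horned,male,anc/anc,6,TRUE
variable,Alpines Steinschaf,horned,female,anc/anc,6,TRUE
variable,Alpines Steinschaf,rudiments,male,anc/der,2,TRUE
variable,Alpines Steinschaf,polled,male,der/der,1,TRUE
variable,Alpines Steinschaf,polled,female,anc/der,7,TRUE
variable,Alpines Steinschaf,polled,female,der/der,1,TRUE
variable,Alpines Steinschaf,scurred,male,der/der,1,FALSE
variable,Walachenschaf,horned,male,anc/anc,4,TRUE
variable,Walachenschaf,horned,male,anc/der,1,TRUE
variable,Walachenschaf,horned,female,anc/anc,5,TRUE
variable,Walachenschaf,rudiments,female,anc/anc,2,TRUE
variable,Walachenschaf,rudiments,female,anc/der,1,TRUE
sex_dependent,Cres,polled,female,anc/anc,1,FALSE
sex_dependent,Cres,polled,female,anc/der,1,TRUE
sex_dependent,Krk,polled,female,der/der,3,TRUE
variable,Travnicka Pramenka,horned,male,anc/anc,2,TRUE
variable,Travnicka Pramenka,horned,female,anc/anc,12,TRUE
variable,Travnicka Pramenka,rudiments,female,anc/anc,6,TRUE
variable,Travnicka Pramenka,rudiments,female,anc/der,1,TRUE
variable,Travnicka Pramenka,polled,male,anc/der,4,TRUE
variable,Travnicka Pramenka,polled,male,der/der,1,TRUE
variable,Travnicka Pramenka,polled,female,anc/anc,13,FALSE
variable,Travnicka Pramenka,polled,female,anc/der,2,TRUE
variable,Travnicka Pramenka,scurred,female,anc/der,2,TRUE
variable,Bovec-like (Krainer Steinschaf),horned,male,der/der,5,FALSE
variable,Bovec-like (Krainer Steinschaf),horned,female,der/der,5,FALSE
variable,Bovec-like (Krainer Steinschaf),rudiments,male,der/der,1,FALSE
variable,Bovec-like (Krainer Steinschaf),polled,male,der/der,3,FALSE
variable,Bovec-like (Krainer Steinschaf),polled,female,der/der,8,FALSE
variable,Bovec-like (Krainer Steinschaf),scurred,female,der/der,1,FALSE
variable,Dorper,horned,male,der/der,8,FALSE
variable,Dorper,polled,male,der/der,6,FALSE
variable,Dorper,scurred,male,der/der,3,FALSE
variable,Dorper,scurred,female,der/der,7,FALSE
sex_dependent,Cameroon,horned,male,anc/anc,9,FALSE
sex_dependent,Cameroon,polled,male,anc/anc,3,TRUE
sex_dependent,Cameroon,polled,male,anc/der,1,TRUE
sex_dependent,Cameroon,polled,female,anc/anc,11,FALSE
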