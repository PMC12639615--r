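variant,domain,cohort,pattern,aggregation_call,coloc_call,nuclear_fraction_call,repression_call_ctip2,repression_call_nr4a2,mobility_call,synthetic
p.Ala386Val,CUT1,etiological,anti_dna_aggregate,decreased,decreased,decreased,reduced_repression,reduced_repression,NA,FALSE
p.Arg389Cys,CUT1,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,normal,FALSE
p.Arg389Leu,CUT1,etiological,anti_dna_aggregate,decreased,decreased,decreased,reduced_repression,reduced_repression,NA,FALSE
p.Thr390Ile,CUT1,etiological,anti_dna_aggregate,decreased,decreased,decreased,reduced_repression,reduced_repression,NA,FALSE
p.Gln391Arg,CUT1,etiological,diffuse,normal,normal,normal,reduced_repression,reduced_repression,NA,FALSE
p.Gly392Arg,CUT1,etiological,diffuse,normal,normal,normal,reduced_repression,reduced_repression,NA,FALSE
p.Gly392Glu,CUT1,etiological,anti_dna_aggregate,decreased,decreased,decreased,reduced_repression,reduced_repression,NA,FALSE
p.Gly392Val,CUT1,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,NA,FALSE
p.Glu396Gln,CUT1,etiological,dna_cage,decreased,increased,normal,increased_repression,retained,reduced_mobility,FALSE
p.Arg399His,CUT1,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,normal,FALSE
p.Glu401Lys,CUT1,etiological,dna_cage,decreased,increased,normal,increased_repression,retained,NA,FALSE
p.Glu402Lys,CUT1,etiological,dna_cage,decreased,increased,normal,increased_repression,retained,reduced_mobility,FALSE
p.Gln409Arg,CUT1,etiological,dna_cage,decreased,increased,increased,increased_repression,retained,NA,FALSE
p.Arg429Gln,CUT1,etiological,anti_dna_aggregate,decreased,decreased,decreased,reduced_repression,reduced_repression,NA,FALSE
p.Glu436Val,CUT1,etiological,dna_cage,decreased,increased,increased,increased_repression,retained,reduced_mobility,FALSE
p.Gln514Arg,CUT2,etiological,dna_cage,decreased,increased,normal,increased_repression,retained,reduced_mobility,FALSE
p.Gly515Ser,CUT2,etiological,dna_cage,decreased,increased,normal,increased_repression,retained,reduced_mobility,FALSE
p.Cys518Trp,CUT2,etiological,diffuse,increased,normal,normal,reduced_repression,reduced_repression,normal,FALSE
p.Arg522Cys,CUT2,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,normal,FALSE
p.Glu530Lys,CUT2,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,NA,FALSE
p.Leu545Pro,CUT2,etiological,diffuse,normal,normal,normal,reduced_repression,reduced_repression,NA,FALSE
p.Glu566Lys,CUT2,etiological,dna_cage,decreased,increased,normal,increased_repression,retained,NA,FALSE
CUT1_synthetic_1,CUT1,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,NA,TRUE
CUT1_synthetic_2,CUT1,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,retained,NA,TRUE
CUT1_synthetic_3,CUT1,etiological,anti_dna_aggregate,decreased,normal,normal,reduced_repression,reduced_repression,NA,TRUE
CUT2_synthetic_1,CUT2,etiological,anti_dna_aggregate,decreased,decreased,normal,reduced_repression,reduced_repression,NA,TRUE
CUT2_synthetic_2,CUT2,etiological,anti_dna_aggregate,decreased,decreased,normal,retained,reduced_repression,NA,TRUE
CUT2_synthetic_3,CUT2,etiological,diffuse,normal,normal,normal,reduced_repression,reduced_repression,NA,TRUE
HOX_synthetic_1,HOX,etiological,condensate,decreased,normal,normal,reduced_repression,reduced_repression,NA,TRUE
HOX_synthetic_2,HOX,etiological,condensate,decreased,normal,normal,reduced_repression,reduced_repression,NA,TRUE
HOX_synthetic_3,HOX,etiological,condensate,decreased,decreased,normal,reduced_repression,reduced_repression,NA,TRUE
p.Arg431His,CUT1,population_control,diffuse,normal,normal,normal,retained,retained,NA,FALSE
p.Val554Ile,CUT2,population_control,diffuse,normal,normal,normal,retained,retained,NA,FALSE
p.His646Tyr,HOX,population_control,diffuse,normal,normal,normal,retained,retained,NA,FALSE
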