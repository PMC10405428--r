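format-version: 1.4
ontology: tcell_mini
! Frozen two-cell-type fixture: T cell / mature NK T cell under lymphocyte,
! with decreased-number and absence phenotypes of each, a minimal quality
! hierarchy and a phenotype root.

[Term]
id: CL:0000542
name: lymphocyte
namespace: entity

[Term]
id: CL:0000084
name: T cell
namespace: entity
is_a: CL:0000542 ! lymphocyte

[Term]
id: CL:0000814
name: mature NK T cell
namespace: entity
is_a: CL:0000084 ! T cell

[Term]
id: PATO:0000001
name: quality
namespace: quality

[Term]
id: PATO:0000070
name: amount
namespace: quality
is_a: PATO:0000001 ! quality

[Term]
id: PATO:0001997
name: decreased amount
namespace: quality
is_a: PATO:0000070 ! amount

[Term]
id: PATO:0000462
name: absent
namespace: quality
is_a: PATO:0000070 ! amount

[Term]
id: PATO:0000460
name: abnormal
namespace: quality
is_a: PATO:0000001 ! quality

[Term]
id: MP:0000001
name: mammalian phenotype
namespace: phenotype

[Term]
id: MP:0005018
name: decreased T cell number
namespace: phenotype
is_a: MP:0000001 ! mammalian phenotype
intersection_of: PATO:0001997 ! decreased amount
intersection_of: characteristic_of CL:0000084 ! T cell
intersection_of: has_modifier PATO:0000460 ! abnormal

[Term]
id: MP:0008040
name: decreased NK T cell number
namespace: phenotype
is_a: MP:0000001 ! mammalian phenotype
intersection_of: PATO:0001997 ! decreased amount
intersection_of: characteristic_of CL:0000814 ! mature NK T cell
intersection_of: has_modifier PATO:0000460 ! abnormal

[Term]
id: MP:0008070
name: absent T cells
namespace: phenotype
is_a: MP:0000001 ! mammalian phenotype
intersection_of: PATO:0000462 ! absent
intersection_of: characteristic_of CL:0000084 ! T cell
intersection_of: has_modifier PATO:0000460 ! abnormal

[Term]
id: MP:0008041
name: absent NK T cells
namespace: phenotype
is_a: MP:0000001 ! mammalian phenotype
intersection_of: PATO:0000462 ! absent
intersection_of: characteristic_of CL:0000814 ! mature NK T cell
intersection_of: has_modifier PATO:0000460 ! abnormal
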