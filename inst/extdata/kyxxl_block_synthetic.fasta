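>Hs_Rhino_Q12-F18 synthetic stand-in; K13/P15/L16/L17/F18 as reported
QKAPLLF
>Hs_Rhino_K90-F96 synthetic stand-in; K90/F91/L94/F96 as reported
KFSGLAF
>Hs_Rad17_K194-M200 synthetic stand-in; K194/Y195/L198/M200 as reported
KYSELQM
>Hs_Rad9_K360-F366 synthetic stand-in; K360/F361/R362/L364/F365/F366 as reported
KFRDLFF
>Hs_p21_S153-F159 synthetic stand-in; K154/R155/R156/L157/I158/F159 as reported
SKRRLIF
>variant_01 synthetic orthologue stand-in (group 1)
KYTPLVF
>variant_02 synthetic orthologue stand-in (group 1)
RYAELSW
>variant_03 synthetic orthologue stand-in (group 1)
KKSPLLY
>variant_04 synthetic orthologue stand-in (group 1)
RFNQLTI
>variant_05 synthetic orthologue stand-in (group 1)
KYGDLAL
>variant_06 synthetic orthologue stand-in (group 2)
TSRELGF
>variant_07 synthetic orthologue stand-in (group 2)
GDRQLAV
>variant_08 synthetic orthologue stand-in (group 2)
ESRNLSM
>variant_09 synthetic orthologue stand-in (group 2)
ADRGLTF
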