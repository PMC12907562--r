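state,surface,ligand_label,interface,hypothetical,partially_specified,description
A,Rad9 front pocket,Rad9 tail,Rad9 T355-A371 & Rad9 CRS,0,0,Default: the Rad9 tail occupies the front pocket and the Hus1 groove; Rad1 is free
A,Hus1 groove,Rad9 tail,Rad9 S291-T313 & Hus1,0,0,Default: the Rad9 tail occupies the front pocket and the Hus1 groove; Rad1 is free
B,Rad9 front pocket,Rad9 tail,Rad9 T355-A371 & Rad9 CRS,0,1,Rad17 recruitment: Rad17 first contacts Rad1 through its N-terminus
B,Hus1 groove,Rad9 tail,Rad9 S291-T313 & Hus1,0,1,Rad17 recruitment: Rad17 first contacts Rad1 through its N-terminus
B,Rad1 surface,Rad17,Rad17 & Rad1,0,1,Rad17 recruitment: Rad17 first contacts Rad1 through its N-terminus
C,Rad9 front pocket,Rad17,Rad17 KYxxL & Rad9 CRS,0,0,Rad17 association: KYxxL displaces the Rad9 tail; iVERGE anchors Hus1
C,Hus1 groove,Rad17,Rad17-iVERGE & Hus1,0,0,Rad17 association: KYxxL displaces the Rad9 tail; iVERGE anchors Hus1
C,Rad1 surface,Rad17,Rad17 & Rad1,0,0,Rad17 association: KYxxL displaces the Rad9 tail; iVERGE anchors Hus1
D,Rad9 front pocket,Rad17,Rad17 KYxxL & Rad9 CRS,0,1,Rhino approach: Rhino T52-F61 takes over the Rad1 surface
D,Hus1 groove,Rad17,Rad17-iVERGE & Hus1,0,1,Rhino approach: Rhino T52-F61 takes over the Rad1 surface
D,Rad1 surface,Rhino,Rhino T52-F61 & Rad1,0,1,Rhino approach: Rhino T52-F61 takes over the Rad1 surface
E,Rad9 front pocket,Rad17,Rad17 KYxxL & Rad9 CRS,1,1,Rhino insertion: T38-I48 wedges in while KYxxL is still bound (simultaneous occupancy may clash)
E,Hus1 groove,Rad17,Rad17-iVERGE & Hus1,1,1,Rhino insertion: T38-I48 wedges in while KYxxL is still bound (simultaneous occupancy may clash)
E,Rad1 surface,Rhino,Rhino T38-I48 & Rad1,1,1,Rhino insertion: T38-I48 wedges in while KYxxL is still bound (simultaneous occupancy may clash)
E,Rad1 surface,Rhino,Rhino T52-F61 & Rad1,1,1,Rhino insertion: T38-I48 wedges in while KYxxL is still bound (simultaneous occupancy may clash)
F,Rad9 front pocket,Rhino,Rhino P10-A31 & Rad9 CRS,0,0,Rhino association: Rhino replaces Rad17 on Rad9 and Rad1; iVERGE stays on Hus1
F,Hus1 groove,Rad17,Rad17-iVERGE & Hus1,0,0,Rhino association: Rhino replaces Rad17 on Rad9 and Rad1; iVERGE stays on Hus1
F,Rad1 surface,Rhino,Rhino T38-I48 & Rad1,0,0,Rhino association: Rhino replaces Rad17 on Rad9 and Rad1; iVERGE stays on Hus1
F,Rad1 surface,Rhino,Rhino T52-F61 & Rad1,0,0,Rhino association: Rhino replaces Rad17 on Rad9 and Rad1; iVERGE stays on Hus1
G,Rad9 front pocket,Rhino,Rhino S83-S98 & Rad9 CRS,0,0,Polymerize: the second KYxxL+ motif bridges the adjacent clamp's Rad9
G,Hus1 groove,Rad17,Rad17-iVERGE & Hus1,0,0,Polymerize: the second KYxxL+ motif bridges the adjacent clamp's Rad9
G,Rad1 surface,Rhino,Rhino T38-I48 & Rad1,0,0,Polymerize: the second KYxxL+ motif bridges the adjacent clamp's Rad9
G,Rad1 surface,Rhino,Rhino T52-F61 & Rad1,0,0,Polymerize: the second KYxxL+ motif bridges the adjacent clamp's Rad9
H,Rad9 front pocket,Rad9 tail,Rad9 T355-A371 & Rad9 CRS,0,0,Depolymerize: the Rad9 tail displaces Rhino K90-F96 and the iVERGE
H,Hus1 groove,Rad9 tail,Rad9 S291-T313 & Hus1,0,0,Depolymerize: the Rad9 tail displaces Rhino K90-F96 and the iVERGE
H,Rad1 surface,Rhino,Rhino T38-I48 & Rad1,0,0,Depolymerize: the Rad9 tail displaces Rhino K90-F96 and the iVERGE
H,Rad1 surface,Rhino,Rhino T52-F61 & Rad1,0,0,Depolymerize: the Rad9 tail displaces Rhino K90-F96 and the iVERGE
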