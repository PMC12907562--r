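ligand_label,receptor_label,dg_bind,buried_area,source
Rad17 KYxxL,Rad9 CRS,-1327,1041,PDB 7Z6H; prior FMO study
Rhino P10-A31,Rad9 CRS,-610,1417,this dataset
Rhino S83-S98,Rad9 CRS,-515,981,this dataset
Rad9 T355-A371,Rad9 CRS,-461,934,this dataset
p21,Rad9 CRS,-415,993,this dataset
Rad17,Rad1,-293,707,PDB 8GNN; prior FMO study
Rhino T38-I48,Rad1,-482,812,this dataset
Rhino T52-F61,Rad1,-381,945,this dataset
Rad17-iVERGE,Hus1,-693,627,prior FMO study
Rad9 S291-T313,Hus1,-635,956,this dataset
RFC2,Rad9/Rad1,41,403,PDB 7Z6H; prior FMO study
RFC5,Rad1,8,706,PDB 7Z6H; prior FMO study
RFC4,Rad1,93,286,PDB 7Z6H; prior FMO study
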