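descriptor,category,dim_tag,selected_pca
N-072,Atom centered fragments,1D,FALSE
C-012,Atom centered fragments,1D,TRUE
O-060,Atom centered fragments,1D,FALSE
nCO,functional groups,1D,FALSE
nCrR2,functional groups,1D,FALSE
MLOGP,properties,1D,TRUE
MATS4v,2D autocorrelations,2D,FALSE
GATS8p,2D autocorrelations,2D,FALSE
GATS6e,2D autocorrelations,2D,TRUE
ATS5e,2D autocorrelations,2D,FALSE
MATS7e,2D autocorrelations,2D,FALSE
SIC0,Topological descriptors,2D,FALSE
piPC10,Topological descriptors,2D,FALSE
PCD,Topological descriptors,2D,FALSE
PJI2,Topological descriptors,2D,TRUE
Mor31m,3D-MoRSE descriptors,3D,FALSE
Mor17e,3D-MoRSE descriptors,3D,FALSE
Mor12p,3D-MoRSE descriptors,3D,TRUE
HOMA,aromaticity indices,3D,FALSE
HATS1u,GETAWAY descriptors,3D,FALSE
R5e+,GETAWAY descriptors,3D,FALSE
R4e,GETAWAY descriptors,3D,TRUE
H8e,GETAWAY descriptors,3D,FALSE
RDF070m,RDF descriptors,3D,TRUE
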