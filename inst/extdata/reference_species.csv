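species_id,binomial,family,life_form,leaf_shape,texture,cluster
LiLu,Ligustrum lucidum,Oleaceae,tree,Ovate to broadly elliptic,Leathery,3
CeDe,Cedrus deodara,Pinaceae,tree,Needle,Leathery,3
PiTa,Pinus tabuliformis,Pinaceae,tree,Needle,Leathery,1
PiBu,Pinus bungeana,Pinaceae,tree,Needle,Leathery,1
ViOd,Viburnum odoratissimum,Caprifoliaceae,shrub,Elliptic to obovate,Leathery,3
PiTo,Pittosporum tobira,Pittosporaceae,shrub,Obovate or obovate lanceolate,Leathery,3
BuSi,Buxus sinica,Buxaceae,shrub,Obovate to oblong ovate,Leathery,1
PhSe,Photinia serrulata,Rosaceae,shrub,Obovate or obovate ellipse,Leathery,3
InTe,Indocalamus tessellatus,Gramineae,herb,Elliptic lanceolate,Papery,1
PhVi,Phyllostachys viridis,Gramineae,herb,Oblong lanceolate or lanceolate,Papery,1
TrFo,Trachycarpus fortunei,Palmae,tree-dwelling,3/4 orbicular or suborbicular,Leathery,2
MaGr,Magnolia grandiflora,Magnoliaceae,tree,Ellipse to obovate ellipse,Leathery,3
ErJa,Eriobotrya japonica,Rosaceae,tree,Lanceolate to oblong,Leathery,2
OsFr,Osmanthus fragrans,Oleaceae,tree,Elliptic to elliptic lanceolate,Leathery,2
PlOr,Platycladus orientalis,Cupressaceae,tree,Squamiform,Leathery,2
TrRe,Trifolium repens,Leguminosae,herb,Ternate palmate leaf,Papery,1
JaMe,Jasminum mesnyi,Oleaceae,shrub,Compound,Leathery,2
IlCo,Ilex cornuta,Aquifoliaceae,shrub,Quadrangular oblong or ovate,Leathery,2
FaJa,Fatsia japonica,Araliaceae,shrub,Palmate lobed,Leathery,2
NaDo,Nandina domestica,Berberidaceae,shrub,Elliptic or elliptic lanceolate,Leathery,2
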