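# TPE-FLIM reference distributions for dermal and epidermal cell classes.
# Per-class bi-exponential decay parameters (mean, sd): tau1/tau2 short/long
# lifetime (ps), taum amplitude-weighted mean lifetime (ps, documentation
# only -- samples derive taum from tau1/tau2/a1/a2), amp_ratio = a1/a2,
# intensity in photons/mW. group_label: 0 = M1 macrophage, 1 = M2 macrophage,
# 2 = other dermal cell. n_cells: per-class counts used for dataset assembly
# (399 cells over the in_model rows). Rows marked standin=TRUE (ex vivo and
# in vivo mast cells) have no published parameter row of their own: they are
# synthetic stand-ins using the in vitro resting mast cell means with SDs
# scaled by the in-vivo/in-vitro SD ratio (~0.4) seen for the macrophage
# classes measured in both environments, consistent with the reported
# non-superimposition of mast-cell and macrophage TPE-FLIM signatures.
# The monocyte row is a reference distribution only (in_model=FALSE).
class_name,group_label,environment,n_cells,tau1_mean,tau1_sd,tau2_mean,tau2_sd,taum_mean,taum_sd,amp_ratio_mean,amp_ratio_sd,intensity_mean,intensity_sd,in_model,standin
Monocyte-derived M1-polarised macrophages,0,in_vitro,21,163,50,1209,161,479,106,2.4,0.6,600,100,TRUE,FALSE
Monocyte-derived M2-polarised macrophages,1,in_vitro,27,417,134,2305,194,1185,170,2.3,0.5,500,100,TRUE,FALSE
M1 isolated dermal macrophages,0,in_vitro,34,225,84,1289,278,461,175,4.8,3.4,3000,500,TRUE,FALSE
M2 isolated dermal macrophages,1,in_vitro,28,807,250,2352,229,1281,155,2.2,1.1,800,200,TRUE,FALSE
Ex vivo M1 macrophages (CD68),0,ex_vivo,8,190,38,1504,133,458,50,4.1,0.7,3000,500,TRUE,FALSE
Ex vivo M2 macrophages (CD163),1,ex_vivo,12,498,129,2267,155,1369,201,1.1,0.4,700,300,TRUE,FALSE
In vivo M1 macrophages,0,in_vivo,40,196,40,1698,172,477,105,5.0,2.8,686,165,TRUE,FALSE
In vivo phagocytosing M1 macrophages,0,in_vivo,2,105,10,1272,89,195,44,14.7,4.5,1100,150,TRUE,FALSE
In vivo M2 macrophages,1,in_vivo,28,442,54,2458,90,1407,60,1.2,0.2,360,155,TRUE,FALSE
Resting mast cells,2,in_vitro,45,533,266,2289,317,1248,287,1.5,0.5,1300,400,TRUE,FALSE
Activated mast cells,2,in_vitro,14,288,130,1920,287,862,268,2.5,2.0,900,200,TRUE,FALSE
Ex vivo mast cells (stand-in),2,ex_vivo,17,533,106,2289,127,1248,115,1.5,0.2,1300,160,TRUE,TRUE
In vivo mast cells (stand-in),2,in_vivo,82,533,106,2289,127,1248,115,1.5,0.2,1300,160,TRUE,TRUE
Dendritic cells,2,in_vitro,14,434,188,2578,328,1265,180,1.6,0.2,538,258,TRUE,FALSE
Fibroblasts,2,in_vitro,6,429,51,1983,137,921,81,0.5,0.1,469,137,TRUE,FALSE
Neutrophils,2,in_vitro,21,714,250,1795,600,1074,109,1.5,0.5,500,115,TRUE,FALSE
PBMC-derived monocytes,2,in_vitro,15,491,130,2025,301,989,111,1.8,0.5,700,130,FALSE,FALSE
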