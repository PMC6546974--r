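gene,parameter,category,weight
HLA-A,HLA_A,MHC,1
HLA-B,HLA_B,MHC,1
HLA-C,HLA_C,MHC,1
HLA-DPA1,HLA_DPA1,MHC,1
HLA-DPB1,HLA_DPB1,MHC,1
HLA-E,HLA_E,MHC,1
HLA-F,HLA_F,MHC,1
TAP1,TAP1,MHC,1
TAP2,TAP2,MHC,1
B2M,B2M,MHC,1
PDCD1,PD1,CP,-1
CD274,PDL1,CP,-1
PDCD1LG2,PDL2,CP,-1
CTLA4,CTLA4,CP,-1
LAG3,LAG3,CP,-1
HAVCR2,TIM3,CP,-1
TIGIT,TIGIT,CP,-1
CD27,CD27,CP,1
ICOS,ICOS,CP,1
CD28,CD28,CP,1
CD8A,Act_CD8,EC,1
CD8B,Act_CD8,EC,1
GZMA,Act_CD8,EC,1
GZMB,Act_CD8,EC,1
PRF1,Act_CD8,EC,1
IFNG,Act_CD8,EC,1
CD4,Act_CD4,EC,1
IL2,Act_CD4,EC,1
CD69,Act_CD4,EC,1
TNF,Act_CD4,EC,1
EOMES,Tem_CD8,EC,1
KLRG1,Tem_CD8,EC,1
CX3CR1,Tem_CD8,EC,1
CCR7,Tem_CD4,EC,1
SELL,Tem_CD4,EC,1
IL7R,Tem_CD4,EC,1
FOXP3,Treg,SC,-1
IL2RA,Treg,SC,-1
IKZF2,Treg,SC,-1
CCR8,Treg,SC,-1
ARG1,MDSC,SC,-1
NOS2,MDSC,SC,-1
CD33,MDSC,SC,-1
ITGAM,MDSC,SC,-1
S100A8,MDSC,SC,-1
S100A9,MDSC,SC,-1
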