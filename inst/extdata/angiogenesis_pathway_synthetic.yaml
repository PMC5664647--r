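genes:
  VEGFA:
  - VEGFA_snp1
  - VEGFA_snp2
  - VEGFA_snp3
  - VEGFA_snp4
  - VEGFA_snp5
  - VEGFA_snp6
  - VEGFA_snp7
  - VEGFA_snp8
  FLT1:
  - FLT1_snp1
  - FLT1_snp2
  - FLT1_snp3
  - FLT1_snp4
  - FLT1_snp5
  - FLT1_snp6
  - FLT1_snp7
  - FLT1_snp8
  KDR:
  - rs6838752
  - KDR_snp1
  - KDR_snp2
  - KDR_snp3
  - KDR_snp4
  - KDR_snp5
  - KDR_snp6
  - KDR_snp7
  HIF1A:
  - HIF1A_snp1
  - HIF1A_snp2
  - HIF1A_snp3
  - HIF1A_snp4
  - HIF1A_snp5
  - HIF1A_snp6
  - HIF1A_snp7
  - HIF1A_snp8
  PDGFB:
  - rs4821877
  - PDGFB_snp1
  - PDGFB_snp2
  - PDGFB_snp3
  - PDGFB_snp4
  - PDGFB_snp5
  - PDGFB_snp6
  - PDGFB_snp7
  TEK:
  - TEK_snp1
  - TEK_snp2
  - TEK_snp3
  - TEK_snp4
  - TEK_snp5
  - TEK_snp6
  - TEK_snp7
  - TEK_snp8
  TGFB1:
  - TGFB1_snp1
  - TGFB1_snp2
  - TGFB1_snp3
  - TGFB1_snp4
  - TGFB1_snp5
  - TGFB1_snp6
  - TGFB1_snp7
  - TGFB1_snp8
  TGFBR1:
  - TGFBR1_snp1
  - TGFBR1_snp2
  - TGFBR1_snp3
  - TGFBR1_snp4
  - TGFBR1_snp5
  - TGFBR1_snp6
  - TGFBR1_snp7
  - TGFBR1_snp8
  IGF1R:
  - rs2139924
  - IGF1R_snp1
  - IGF1R_snp2
  - IGF1R_snp3
  - IGF1R_snp4
  - IGF1R_snp5
  - IGF1R_snp6
  - IGF1R_snp7
  NFKB1:
  - NFKB1_snp1
  - NFKB1_snp2
  - NFKB1_snp3
  - NFKB1_snp4
  - NFKB1_snp5
  - NFKB1_snp6
  - NFKB1_snp7
  - NFKB1_snp8
  CXCL8:
  - CXCL8_snp1
  - CXCL8_snp2
  - CXCL8_snp3
  - CXCL8_snp4
  - CXCL8_snp5
  - CXCL8_snp6
  - CXCL8_snp7
  - CXCL8_snp8
  CXCR1:
  - rs1008562
  - CXCR1_snp1
  - CXCR1_snp2
  - CXCR1_snp3
  - CXCR1_snp4
  - CXCR1_snp5
  - CXCR1_snp6
  - CXCR1_snp7
  CXCR2:
  - CXCR2_snp1
  - CXCR2_snp2
  - CXCR2_snp3
  - CXCR2_snp4
  - CXCR2_snp5
  - CXCR2_snp6
  - CXCR2_snp7
  - CXCR2_snp8
  IL1A:
  - IL1A_snp1
  - IL1A_snp2
  - IL1A_snp3
  - IL1A_snp4
  - IL1A_snp5
  - IL1A_snp6
  - IL1A_snp7
  - IL1A_snp8
  IL1B:
  - IL1B_snp1
  - IL1B_snp2
  - IL1B_snp3
  - IL1B_snp4
  - IL1B_snp5
  - IL1B_snp6
  - IL1B_snp7
  - IL1B_snp8
  TNF:
  - rs1800630
  - TNF_snp1
  - TNF_snp2
  - TNF_snp3
  - TNF_snp4
  - TNF_snp5
  - TNF_snp6
  - TNF_snp7
  MMP1:
  - rs470215
  - MMP1_snp1
  - MMP1_snp2
  - MMP1_snp3
  - MMP1_snp4
  - MMP1_snp5
  - MMP1_snp6
  - MMP1_snp7
  MMP3:
  - MMP3_snp1
  - MMP3_snp2
  - MMP3_snp3
  - MMP3_snp4
  - MMP3_snp5
  - MMP3_snp6
  - MMP3_snp7
  - MMP3_snp8
  MMP7:
  - MMP7_snp1
  - MMP7_snp2
  - MMP7_snp3
  - MMP7_snp4
  - MMP7_snp5
  - MMP7_snp6
  - MMP7_snp7
  - MMP7_snp8
  MMP9:
  - MMP9_snp1
  - MMP9_snp2
  - MMP9_snp3
  - MMP9_snp4
  - MMP9_snp5
  - MMP9_snp6
  - MMP9_snp7
  BMP1:
  - BMP1_snp1
  - BMP1_snp2
  - BMP1_snp3
  - BMP1_snp4
  - BMP1_snp5
  - BMP1_snp6
  - BMP1_snp7
  BMP2:
  - BMP2_snp1
  - BMP2_snp2
  - BMP2_snp3
  - BMP2_snp4
  - BMP2_snp5
  - BMP2_snp6
  - BMP2_snp7
  BMP4:
  - BMP4_snp1
  - BMP4_snp2
  - BMP4_snp3
  - BMP4_snp4
  - BMP4_snp5
  - BMP4_snp6
  - BMP4_snp7
  BMPR1A:
  - BMPR1A_snp1
  - BMPR1A_snp2
  - BMPR1A_snp3
  - BMPR1A_snp4
  - BMPR1A_snp5
  - BMPR1A_snp6
  - BMPR1A_snp7
  BMPR1B:
  - BMPR1B_snp1
  - BMPR1B_snp2
  - BMPR1B_snp3
  - BMPR1B_snp4
  - BMPR1B_snp5
  - BMPR1B_snp6
  - BMPR1B_snp7
  BMPR2:
  - BMPR2_snp1
  - BMPR2_snp2
  - BMPR2_snp3
  - BMPR2_snp4
  - BMPR2_snp5
  - BMPR2_snp6
  - BMPR2_snp7
  GDF10:
  - GDF10_snp1
  - GDF10_snp2
  - GDF10_snp3
  - GDF10_snp4
  - GDF10_snp5
  - GDF10_snp6
  - GDF10_snp7
  TLR2:
  - rs7656411
  - TLR2_snp1
  - TLR2_snp2
  - TLR2_snp3
  - TLR2_snp4
  - TLR2_snp5
  - TLR2_snp6
  TLR3:
  - TLR3_snp1
  - TLR3_snp2
  - TLR3_snp3
  - TLR3_snp4
  - TLR3_snp5
  - TLR3_snp6
  - TLR3_snp7
  TLR4:
  - rs1927911
  - rs11536889
  - TLR4_snp1
  - TLR4_snp2
  - TLR4_snp3
  - TLR4_snp4
  - TLR4_snp5
  EGR2:
  - rs2295814
  - rs224082
  - EGR2_snp1
  - EGR2_snp2
  - EGR2_snp3
  - EGR2_snp4
  - EGR2_snp5
  EGFR:
  - rs17151957
  - EGFR_snp1
  - EGFR_snp2
  - EGFR_snp3
  - EGFR_snp4
  - EGFR_snp5
  - EGFR_snp6
  IRS1:
  - IRS1_snp1
  - IRS1_snp2
  - IRS1_snp3
  - IRS1_snp4
  - IRS1_snp5
  - IRS1_snp6
  - IRS1_snp7
  VDR:
  - VDR_snp1
  - VDR_snp2
  - VDR_snp3
  - VDR_snp4
  - VDR_snp5
  - VDR_snp6
  - VDR_snp7
subpathways:
  vegf_receptor:
  - VEGFA
  - FLT1
  - KDR
  hypoxia:
  - HIF1A
  - EGR2
  pdgf_tek:
  - PDGFB
  - TEK
  tgf_beta:
  - TGFB1
  - TGFBR1
  igf:
  - IGF1R
  - IRS1
  inflammation:
  - NFKB1
  - CXCL8
  - CXCR1
  - CXCR2
  - IL1A
  - IL1B
  - TNF
  mmp:
  - MMP1
  - MMP3
  - MMP7
  - MMP9
  bmp:
  - BMP1
  - BMP2
  - BMP4
  - BMPR1A
  - BMPR1B
  - BMPR2
  - GDF10
  tlr_egfr:
  - TLR2
  - TLR3
  - TLR4
  - EGFR
  - VDR
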