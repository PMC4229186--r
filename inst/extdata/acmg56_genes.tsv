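#gene	lof_actionable
APC	TRUE
MYH11	FALSE
ACTA2	FALSE
TMEM43	TRUE
DSP	TRUE
PKP2	TRUE
DSG2	TRUE
DSC2	TRUE
SCN5A	TRUE
RYR2	TRUE
LMNA	TRUE
MYBPC3	TRUE
MYH7	FALSE
TNNT2	TRUE
TNNI3	FALSE
TPM1	FALSE
MYL3	FALSE
ACTC1	FALSE
PRKAG2	FALSE
GLA	TRUE
MYL2	FALSE
LDLR	TRUE
APOB	TRUE
PCSK9	TRUE
BRCA1	TRUE
BRCA2	TRUE
SDHD	TRUE
SDHAF2	TRUE
SDHC	TRUE
SDHB	TRUE
TSC1	TRUE
TSC2	TRUE
VHL	TRUE
WT1	TRUE
NF2	TRUE
COL3A1	TRUE
FBN1	TRUE
TGFBR1	TRUE
TGFBR2	TRUE
SMAD3	TRUE
KCNQ1	TRUE
KCNH2	TRUE
MLH1	TRUE
MSH2	TRUE
MSH6	TRUE
PMS2	TRUE
MUTYH	TRUE
MEN1	TRUE
RET	TRUE
PTEN	TRUE
RB1	TRUE
STK11	TRUE
TP53	TRUE
MYLK	TRUE
RYR1	FALSE
CACNA1S	FALSE
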