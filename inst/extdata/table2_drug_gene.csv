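agent,gene,direction
17-β-estradiol,CALML5,downregulates
Fenretinide,CALML5,downregulates
Valproic acid,CALML5,downregulates
17-β-estradiol,S100A7,upregulates
Isotretinoin,S100A7,upregulates
Alitretinoin,S100A7,upregulates
Tretinoin,S100A7,upregulates
4-oxoretinoic acid,S100A7,upregulates
Calcitriol,S100A7,upregulates
Fenretinide,KRT16,downregulates
Isotretinoin,KRT16,downregulates
Calcipotriol,KRT16,downregulates
Folic acid,KRT16,downregulates
Ivermectin,KRT16,downregulates
Acetaminophen,KRT16,downregulates
Calcipotriol,KRT16,upregulates
Cisplatin,KRT16,upregulates
17-β-estradiol,KRT16,upregulates
5-fluorouracil,KRT16,upregulates
Gentamycin,KRT16,upregulates
Metronidazole,KRT16,upregulates
Tretinoin,DEFB4A,downregulates
17-β-estradiol,DEFB4A,upregulates
Progesterone,DEFB4A,upregulates
17-β-estradiol,KRT6B,downregulates
Calcitriol,KRT6B,upregulates
Progesterone,KRT6B,upregulates
17-β-estradiol,KRT6B,upregulates
Folic acid,KRT14,downregulates
Isotretinoin,KRT14,downregulates
Ivermectin,KRT14,downregulates
Acetaminophen,KRT14,downregulates
Dexamethasone,KRT14,downregulates
Methimazole,KRT14,downregulates
17-β-estradiol,KRT14,upregulates
Tretinoin,KRT14,upregulates
17-β-estradiol,DSG1,downregulates
Retinoic acid,DSG1,downregulates
Valproic acid,DEFB103A,downregulates
Folic acid,DEFB103A,upregulates
Folic acid,CASP14,downregulates
Acetaminophen,CASP14,downregulates
17-β-estradiol,CRABP2,downregulates
Dexamethasone,CRABP2,downregulates
Valproic acid,CRABP2,downregulates
Retinoic acid,CRABP2,upregulates
Gentamycin,CRABP2,upregulates
Valproic acid,CRABP2,upregulates
Valproic acid,C16orf82,downregulates
Levofloxacin,C11orf65,upregulates
Cilastatin,DPEP1,downregulates
Gentamicin,DPEP1,downregulates
Methimazole,DPEP1,downregulates
Mifepristone,DPEP1,downregulates
Acetaminophen,DPEP1,downregulates
Valproic acid,DPEP1,downregulates
Dexamethasone,DPEP1,upregulates
Doxorubicin,DPEP1,upregulates
Progesterone,DPEP1,upregulates
Vancomycin,DPEP1,upregulates
17-β-estradiol,PRB3,downregulates
17-β-estradiol,PRB3,upregulates
Acetaminophen,NPAT,downregulates
Valproic acid,NPAT,downregulates
Valproic acid,NPAT,upregulates
Tretinoin,ATM,downregulates
17-β-estradiol,ATM,downregulates
Calcitriol,ATM,downregulates
Cisplatin,ATM,downregulates
Doxorubicin,ATM,downregulates
Rifampicin,ATM,downregulates
Valproic acid,ATM,downregulates
17-β-estradiol,ATM,upregulates
Doxorubicin,ATM,upregulates
Gentamycin,ATM,upregulates
Acetaminophen,ATM,upregulates
Valproic acid,ATM,upregulates
17-β-estradiol,CASP8,downregulates
5-fluorouracil,CASP8,downregulates
Doxorubicin,CASP8,downregulates
17-β-estradiol,CASP8,upregulates
5-fluorouracil,CASP8,upregulates
Alitretinoin,CASP8,upregulates
Isotretinoin,CASP8,upregulates
Cisplatin,CASP8,upregulates
Dexamethasone,CASP8,upregulates
Diclofenac,CASP8,upregulates
Doxorubicin,CASP8,upregulates
Gentamicin,CASP8,upregulates
Methotrexate,CASP8,upregulates
Mitomycin,CASP8,upregulates
Paclitaxel,CASP8,upregulates
Acetaminophen,CASP8,upregulates
Progesterone,CASP8,upregulates
Valproic acid,CASP8,upregulates
Vincristine,CASP8,upregulates
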