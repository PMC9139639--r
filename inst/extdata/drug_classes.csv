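code,class
oxaliplatin,CHEMO
irinotecan,CHEMO
trifluridine_tipiracil,CHEMO
fluorouracil,FLUOROURACIL
capecitabine,FLUOROURACIL
bevacizumab,BEVACIZUMAB
ramucirumab,VEGF
aflibercept,VEGF
cetuximab,EGFR
panitumumab,EGFR
encorafenib,BRAF
trastuzumab,ERBB2
lapatinib,ERBB2
trastuzumab_deruxtecan,ERBB2
larotrectinib,NTRK
pembrolizumab,ICI
nivolumab,ICI
ipilimumab,ICI
regorafenib,OTHER_TARGETED
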