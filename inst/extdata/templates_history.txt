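History of breast cancer treated with mastectomy in {YEAR}
She is status post lumpectomy of the {LAT} breast in {YEAR}
Pathology from the benign biopsy of the {LAT} breast was reviewed
She completed adjuvant chemotherapy and radiotherapy in {YEAR}
Mammogram showed a stable breast mass in the {LAT} breast
Her surgical excision site is healing well
She underwent a wide local excision with clear margins in {YEAR}
Personal history of breast cancer followed in our clinic
Known history of dcis of the {LAT} breast treated in {YEAR}
Her prior breast carcinoma was treated with breast conserving surgery
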