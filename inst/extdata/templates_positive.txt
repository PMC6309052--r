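Now with newly diagnosed DCIS recurrence
She was found to have an ipsilateral breast tumor recurrence
Is currently receiving chemotherapy for her recurrent breast cancer
She initially received breast conserving therapy for a {LAT} breast cancer in {YEAR} and now presents with an ipsilateral breast tumor recurrence
She was recently diagnosed with a cancer in the ipsilateral breast
Biopsy of the {LAT} breast confirmed a local recurrence in the lumpectomy bed
She underwent excision of a chest wall recurrence after mastectomy in {YEAR}
Pathology from the {LAT} breast demonstrated recurrent infiltrating ductal carcinoma
Imaging and biopsy are consistent with a chest wall breast cancer recurrence
Now presents with a {LAT} sided breast tumor recurrence
Female with h o recurrent breast ca now status post excision of a chest wall recurrence
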