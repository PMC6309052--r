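cui	preferred_name
C1997028	History of malignant neoplasm of breast
C1387407	Personal history of primary malignant neoplasm of breast
C2945760	Recurrent
C0278493	Recurrent breast cancer
C0920420	Cancer recurrence
C1458156	Recurrent Malignant Neoplasm
C0235653	Malignant neoplasm of female breast
C0277556	Recurrent disease
C1512083	Ductal
C0007124	Noninfiltrating Intraductal Carcinoma
C0222600	Right breast
C0205090	Right
C0262512	History of present illness
C4042789	Right-Sided Breast Neoplasms
C0006142	Malignant neoplasm of breast
C0222601	Left breast
C0205091	Left
C0441987	Ipsilateral
C0205276	Local
C0034897	Recurrence
C1883727	Local recurrence of malignant tumor
C0024881	Mastectomy
C0851238	Lumpectomy
C0728940	Excision
C0005558	Biopsy
C0817096	Chest wall structure
C1275664	Tumor bed
C0178738	Breast conserving surgery
C1522449	Radiotherapy
C1527349	Ductal carcinoma in situ
C0279563	Infiltrating ductal carcinoma
C0279565	Infiltrating lobular carcinoma
C0577559	Mass of breast
C1518422	Newly diagnosed
C0013216	Chemotherapy
C0006826	Malignant neoplasm
C1709926	Recurrent tumor
C1299994	Breast tumor
C0585362	Wide local excision
C1514893	Re-excision
C2732294	Chest wall recurrence
C5200001	Ipsilateral breast tumor recurrence
C5200002	Recurrent ductal carcinoma in situ
C5200003	Locoregional recurrence
C0740175	Positive surgical margin
C5200004	New primary malignant neoplasm
C0262926	History of
C0439849	Relapse
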