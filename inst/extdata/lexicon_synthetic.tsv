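cui	preferred_name	surface_form	score
C1997028	History of malignant neoplasm of breast	history of recurrent breast cancer	1.0
C1997028	History of malignant neoplasm of breast	history of breast cancer	1.0
C1387407	Personal history of primary malignant neoplasm of breast	personal history of breast cancer	1.0
C1387407	Personal history of primary malignant neoplasm of breast	personal history of primary breast cancer	1.0
C2945760	Recurrent	recurrent	2.0
C1458156	Recurrent Malignant Neoplasm	recurrent	1.0
C0278493	Recurrent breast cancer	recurrent breast cancer	1.0
C0278493	Recurrent breast cancer	recurrent breast ca	1.0
C0920420	Cancer recurrence	cancer recurrence	1.0
C0920420	Cancer recurrence	breast cancer recurrence	1.0
C0920420	Cancer recurrence	recurrence	1.0
C1458156	Recurrent Malignant Neoplasm	recurrent malignant neoplasm	1.0
C1458156	Recurrent Malignant Neoplasm	recurrent malignancy	1.0
C0235653	Malignant neoplasm of female breast	malignant neoplasm of female breast	1.0
C0235653	Malignant neoplasm of female breast	carcinoma of the breast	1.0
C0277556	Recurrent disease	recurrent disease	1.0
C1512083	Ductal	ductal	1.0
C0007124	Noninfiltrating Intraductal Carcinoma	dcis	2.0
C0007124	Noninfiltrating Intraductal Carcinoma	noninfiltrating intraductal carcinoma	1.0
C0007124	Noninfiltrating Intraductal Carcinoma	intraductal carcinoma	1.0
C0222600	Right breast	right breast	1.0
C0205090	Right	right	1.0
C0262512	History of present illness	history of present illness	1.0
C4042789	Right-Sided Breast Neoplasms	right sided breast tumor	1.0
C4042789	Right-Sided Breast Neoplasms	right sided breast cancer	1.0
C0006142	Malignant neoplasm of breast	breast cancer	2.0
C0006142	Malignant neoplasm of breast	breast ca	1.0
C0006142	Malignant neoplasm of breast	breast carcinoma	1.0
C0222601	Left breast	left breast	1.0
C0205091	Left	left	1.0
C0441987	Ipsilateral	ipsilateral	1.0
C0205276	Local	local	1.0
C0034897	Recurrence	recurrence	3.0
C1883727	Local recurrence of malignant tumor	local recurrence	1.0
C0024881	Mastectomy	mastectomy	1.0
C0851238	Lumpectomy	lumpectomy	1.0
C0728940	Excision	excision	1.0
C0005558	Biopsy	biopsy	1.0
C0817096	Chest wall structure	chest wall	1.0
C1275664	Tumor bed	tumor bed	1.0
C1275664	Tumor bed	lumpectomy bed	1.0
C0178738	Breast conserving surgery	breast conserving surgery	1.0
C0178738	Breast conserving surgery	breast conserving therapy	1.0
C1522449	Radiotherapy	radiotherapy	1.0
C1522449	Radiotherapy	radiation therapy	1.0
C1527349	Ductal carcinoma in situ	ductal carcinoma in situ	1.0
C0279563	Infiltrating ductal carcinoma	infiltrating ductal carcinoma	1.0
C0279565	Infiltrating lobular carcinoma	infiltrating lobular carcinoma	1.0
C0577559	Mass of breast	breast mass	1.0
C0577559	Mass of breast	breast lump	1.0
C1518422	Newly diagnosed	newly diagnosed	1.0
C0013216	Chemotherapy	chemotherapy	1.0
C0013216	Chemotherapy	chemo	1.0
C0006826	Malignant neoplasm	cancer	1.0
C0006826	Malignant neoplasm	malignancy	1.0
C0006826	Malignant neoplasm	carcinoma	1.0
C1709926	Recurrent tumor	recurrent tumor	1.0
C1709926	Recurrent tumor	tumor recurrence	1.0
C1299994	Breast tumor	breast tumor	1.0
C0585362	Wide local excision	wide local excision	1.0
C1514893	Re-excision	re excision	1.0
C2732294	Chest wall recurrence	chest wall recurrence	1.0
C5200001	Ipsilateral breast tumor recurrence	ipsilateral breast tumor recurrence	1.0
C5200002	Recurrent ductal carcinoma in situ	dcis recurrence	1.0
C5200002	Recurrent ductal carcinoma in situ	recurrent dcis	1.0
C5200003	Locoregional recurrence	local regional recurrence	1.0
C5200003	Locoregional recurrence	locoregional recurrence	1.0
C0740175	Positive surgical margin	positive margin	1.0
C0740175	Positive surgical margin	positive margins	1.0
C5200004	New primary malignant neoplasm	new primary	1.0
C0262926	History of	history of	1.0
C0262926	History of	h o	1.0
C0439849	Relapse	relapse	1.0
C0439849	Relapse	relapsed	1.0
C5900001	Then (conjunction)	then	1.0
C5900002	The (article)	the	1.0
C5900003	To (preposition)	to	1.0
C5900004	Of (preposition)	of	1.0
C5900005	With (preposition)	with	1.0
C5900006	After (preposition)	after	1.0
C5900007	Her (pronoun)	her	1.0
C5900008	For (preposition)	for	1.0
C0231290	Status post	status post	1.0
C0030193	Pain	pain	1.0
C0015967	Fever	fever	1.0
C0015967	Fever	fevers	1.0
C0011570	Depressive disorder	depression	1.0
C0011570	Depressive disorder	depressive symptoms	1.0
C0003467	Anxiety	anxiety	1.0
C0003467	Anxiety	anxious	1.0
C0027627	Neoplasm metastasis	metastasis	1.0
C0027627	Neoplasm metastasis	metastatic disease	1.0
C0027627	Neoplasm metastasis	distant recurrence	1.0
C0027627	Neoplasm metastasis	distant metastasis	1.0
C0742257	Contralateral breast	contralateral breast	1.0
C0742257	Contralateral breast	contralateral	1.0
C0024671	Mammography	mammogram	1.0
C0024671	Mammography	mammography	1.0
C0020538	Hypertensive disease	hypertension	1.0
C0020538	Hypertensive disease	blood pressure	1.0
C0011849	Diabetes mellitus	diabetes	1.0
C0027497	Nausea	nausea	1.0
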