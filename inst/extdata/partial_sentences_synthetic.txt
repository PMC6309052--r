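history of recurrent breast cancer
after her chest wall breast cancer recurrence excision
now with newly diagnosed dcis recurrence
she was found to have an ipsilateral breast tumor recurrence
is currently receiving chemotherapy for her recurrent breast cancer
personal history of breast cancer now with local recurrence
recurrent carcinoma of the breast confirmed on biopsy
imaging consistent with recurrent malignant neoplasm of the chest wall
biopsy confirmed recurrent disease in the tumor bed
history of present illness notable for recurrent breast cancer
new right sided breast tumor recurrence
recurrence versus new primary in the right breast
biopsy proven local recurrence in the lumpectomy bed
recurrent infiltrating ductal carcinoma of the left breast
recurrent infiltrating lobular carcinoma of the right breast
local regional recurrence after breast conserving surgery
chest wall recurrence after mastectomy
recurrent ductal carcinoma in situ of the left breast
dcis recurrence in the ipsilateral breast
relapse of her breast cancer after chemotherapy
wide local excision of the recurrent breast mass
re excision of the lumpectomy bed showed positive margins
recurrent tumor at the mastectomy site
tumor recurrence within the prior surgical field
h o recurrent breast ca treated with radiotherapy
breast cancer recurrence in the lumpectomy bed
cancer recurrence involving the chest wall
local recurrence of her left breast cancer
recurrent malignancy in the right breast
newly diagnosed recurrence after breast conserving therapy
ipsilateral breast tumor recurrence confirmed by biopsy
she presents with a recurrent breast lump
personal history of primary breast cancer now relapsed
recurrent breast cancer involving the chest wall
biopsy of the left breast showed recurrent dcis
locoregional recurrence following mastectomy and radiation therapy
local recurrence at the site of the prior lumpectomy
recurrent tumor in the tumor bed after wide local excision
new breast mass consistent with cancer recurrence
recurrent breast carcinoma after chemotherapy and radiotherapy
recurrence in the right breast after lumpectomy
recurrence in the left breast after breast conserving surgery
ipsilateral recurrence treated with mastectomy
dcis recurrence requiring re excision
history of breast cancer now with chest wall recurrence
recurrent intraductal carcinoma on the left
breast cancer recurrence despite adjuvant radiotherapy
recurrent malignant neoplasm at the excision site
positive margin at re excision for recurrent disease
recurrence of her right sided breast cancer
relapse with a new breast mass in the tumor bed
local recurrence after wide local excision and radiotherapy
recurrent ductal carcinoma in situ requiring mastectomy
tumor recurrence in the ipsilateral breast
newly diagnosed recurrent breast cancer on biopsy
h o dcis now with local recurrence
recurrence at the mastectomy scar on the chest wall
biopsy of the chest wall showed recurrent carcinoma
recurrent disease in the left breast on imaging
excision of a recurrent tumor from the right breast
history of present illness significant for chest wall recurrence
breast conserving surgery complicated by later local recurrence
recurrent infiltrating ductal carcinoma in the lumpectomy bed
recurrent infiltrating lobular carcinoma treated with chemotherapy
right sided breast tumor recurrence after radiation therapy
she was found to have a recurrence near the prior excision
personal history of breast cancer now with dcis recurrence
cancer recurrence confirmed after re excision
recurrent breast ca in the ipsilateral breast
local regional recurrence involving the chest wall
recurrence after mastectomy with positive margins
newly diagnosed local recurrence on surveillance imaging
relapsed breast cancer treated with chemotherapy
recurrent breast mass in the tumor bed
left breast local recurrence after lumpectomy and radiotherapy
right breast recurrence requiring wide local excision
ductal carcinoma in situ recurrence in the right breast
history of recurrent breast cancer status post mastectomy
biopsy proven recurrent malignancy of the chest wall
recurrence of intraductal carcinoma after excision
ipsilateral breast tumor recurrence after breast conserving therapy
h o breast cancer now with a recurrent tumor on the left
new primary versus local recurrence in the ipsilateral breast
local recurrence with positive margins after excision
recurrent carcinoma in the lumpectomy bed on biopsy
chest wall recurrence treated with excision and radiotherapy
recurrence of her breast cancer in the right breast
recurrent dcis with a new breast lump
personal history of breast cancer with locoregional recurrence
tumor recurrence after wide local excision of the left breast
newly diagnosed recurrent malignant neoplasm of the breast
recurrent disease at the tumor bed with positive margin
breast cancer recurrence requiring mastectomy and chemotherapy
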