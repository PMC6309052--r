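We discussed the risk of recurrence at length
There was no evidence of ipsilateral breast tumor recurrence on imaging today
Screening evaluation for possible DCIS recurrence was negative
She denies any fevers chills or night sweats
We will continue to monitor closely for any concerning changes in the chest wall
Discussed measures to decrease the chance of local recurrence after mastectomy
She is worried about a possible recurrence in the left breast
Mammogram of the right breast was unremarkable
We recommend yearly imaging to rule out recurrent disease
We recommended she consider adjuvant chemotherapy and radiotherapy to decrease recurrence risk
Pathology from the prior lumpectomy was reviewed and the margins were discussed at the evaluation
She was concerned about the appearance of the surgical excision site after her mastectomy
There is no newly diagnosed carcinoma and imaging of the breast was unremarkable
Evaluation for recurrent infiltrating ductal carcinoma of the left breast was negative
We recommended breast conserving therapy to reduce the risk of a chest wall recurrence
She is worried about a possible tumor recurrence in the lumpectomy bed
No new right sided breast tumor was found on examination
She denies any breast mass and presents today for routine evaluation
Imaging was recommended to rule out recurrent malignant neoplasm
She recently underwent an evaluation and no recurrence was demonstrated
She is currently receiving her medications and denies any new issues
We were initially concerned but imaging was unremarkable
Biopsy was recommended to rule out a recurrence and the results confirmed no malignancy
Radiotherapy was recommended in {YEAR} to decrease the risk of recurrence
She presents today and denies any breast changes consistent with recurrence
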