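We recommended the patient undergo adjuvant radiation therapy with the goal of decreasing local regional recurrence and possibly increasing the overall long term survival
Carefully explained to her that removing the {LAT} breast would not decrease the risk of recurrence
She presents with recurrence of depressive symptoms associated with new breast cancer diagnosis
Pt very concerned and anxious as some of her friends have been diagnosed with recurrent breast cancer
Despite this stressor she appears to be coping well at present and is dealing well with fear of recurrence and medical issues
We discussed the lifetime risk of developing a local recurrence after breast conserving surgery
There is no evidence of recurrent disease on examination today
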