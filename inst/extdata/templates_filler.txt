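She returns to clinic today for routine follow up
Vital signs are stable and she is in good spirits
Her pain is well controlled on the current regimen
Blood pressure remains well controlled on current medication
Reviewed the current medication list with the patient
She continues to tolerate her medications well
Follow up appointment scheduled in three months
She is eating well and sleeping through the night
Her energy level has improved since the last visit
She remains active and exercises several times a week
Laboratory studies from today were reviewed with the patient
Her diabetes remains well managed on oral therapy
She reports mild nausea that improves with food
The family was present and participated in the discussion
She will return to clinic in six months for a routine visit
Review of systems was otherwise within expected limits
She was counseled on diet and exercise at todays visit
Her sleep has improved with the current bedtime routine
She is doing well now and will continue the current plan
She received a refill of her current medications at todays visit
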