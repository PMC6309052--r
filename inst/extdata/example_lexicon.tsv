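cui	preferred_name	surface_form	score
C1997028	History of malignant neoplasm of breast	history of recurrent breast cancer	1.0
C1387407	Personal history of primary malignant neoplasm of breast	history of recurrent breast	1.0
C2945760	Recurrent	recurrent	1.0
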