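Is currently receiving chemotherapy for her recurrent breast cancer
Now with newly diagnosed DCIS recurrence
She was found to have a breast cancer recurrence
50 y o female with h o recurrent breast ca who presents with fever
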