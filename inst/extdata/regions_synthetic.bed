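chr8	127735000	127736000	OCR1
chr20	47540000	47541000	OCR2
chr12	34770000	34771000	CCR
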