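code,drug_class
d71..,antidepressant
d75..,antidepressant
d76..,antidepressant
d77..,antidepressant
d31..,anxiolytic
d32..,anxiolytic
d11..,hypnotic
d12..,hypnotic
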