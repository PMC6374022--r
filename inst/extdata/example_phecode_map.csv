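icd9,phecode
272.0,272.1
272.4,272.1
401.1,401.1
401.9,401.1
414.00,411.4
414.01,411.4
410.90,411.2
427.31,427.2
250.00,250.2
250.02,250.2
162.9,165.1
305.1,318.0
496,496.0
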