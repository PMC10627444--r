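management_key,Gulf of Mexico,Mid-Atlantic,Northeast,Southeast,West Coast
High-Low-High,129,70,24,149,65
High-High-High,79,56,29,66,23
High-Low-Low,72,25,19,29,49
Low-Low-High,30,54,13,12,49
High-High-Low,86,37,14,9,13
Low-Low-Low,48,94,20,31,89
Low-High-High,22,63,26,23,19
Low-High-Low,71,154,77,26,20
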