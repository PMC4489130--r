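clone_id	count
r2_clone_1	42
r2_clone_2	30
r2_clone_3	10
r2_clone_4	8
r2_clone_5	5
r2_clone_6	5
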