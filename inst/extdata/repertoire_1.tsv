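clone_id	count
r1_clone_1	33
r1_clone_2	29
r1_clone_3	28
r1_clone_4	5
r1_clone_5	4
r1_clone_6	1
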