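sample_id	habitat
S1	A
S2	A
S3	A
S4	A
S5	A
S6	B
S7	B
S8	B
S9	B
S10	B
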