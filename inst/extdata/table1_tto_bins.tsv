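label	count
0-30	708
31-60	296
61-90	217
91-180	410
181-360	527
>360	1669
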