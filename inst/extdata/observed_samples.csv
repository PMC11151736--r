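date,concentration_ng_l
2020-10-26,6.63
2020-11-13,14.3
2021-03-04,27.4
2021-03-18,11.2
2021-04-29,1.71
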