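cohort	diagnosed	total
first_tier_lr_pcr	48	94
undiagnosed_after_two_tiers	31	94
stgd_subcohort	84	95
md_overall	132	168
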