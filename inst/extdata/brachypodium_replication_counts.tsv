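key	value
truth_n_dms	500245
l3_f3_n_dms	368643
l3_f3_shared_with_truth	92989
n_dms_in_dmrs	2672
n_dmrs	448
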