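feature	context	available	n_cms	n_dms
Genic	CG	5945276	1537550	30396
Genic	CHG	6261258	216844	17059
Genic	CHH	17109118	88467	6009
TE	CG	7066299	6736090	29981
TE	CHG	5524931	3560407	144779
TE	CHH	17168841	663269	39990
Promoter	CG	2201304	568236	12658
Promoter	CHG	1833675	265069	17276
Promoter	CHH	5378012	232488	15500
Whole Genome	CG	21814767	11776244	120744
Whole Genome	CHG	19722162	5590834	282440
Whole Genome	CHH	58692551	1413604	97061
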