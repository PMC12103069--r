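# Canonical RING-type E3/E2 interface positions.
# E3 side: author numbering of the shared E3 chain (MuRF1 RING+MFC construct).
# E2 side: reference E2 numbering (UBE2E1 in the packaged workflow).
# Positions on the E2 side follow the packaged reference sequence
# (SPA motif at 140-142 of the UBE2E1 construct).
side	position	role
e3	24	zinc_center_1_PICLE
e3	25	zinc_center_1_PICLE
e3	26	zinc_center_1_PICLE
e3	27	zinc_center_1_PICLE
e3	28	zinc_center_1_PICLE
e3	76	conserved_proline
e3	79	linchpin_arginine
e2_ref	51	alpha1_basic_pair
e2_ref	54	alpha1_basic_pair
e2_ref	108	L4_bulky_hydrophobic
e2_ref	137	pre_SPA_triplet
e2_ref	138	pre_SPA_triplet
e2_ref	139	pre_SPA_triplet
e2_ref	140	SPA_motif
e2_ref	141	SPA_motif
e2_ref	142	SPA_motif
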