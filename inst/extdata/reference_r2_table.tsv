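# Published benchmark of a curated 1143-gene MSC panel: squared correlation (R^2)
# of one target synovial-MSC lot against per-population median log-TPM profiles,
# under three gene sets (curated panel; 1143 random human genes; all 25,193
# human genes). role: target = the reference population itself, other_msc =
# MSCs from other tissues, artificial_msc = iPSC-derived MSCs, non_msc = other.
population	role	r2_panel	r2_random_human	r2_all_human
SyMSC_secondary_lot	target	0.886	0.951	0.947
SyMSC_med	target	0.949	0.977	0.978
BMSC_med	other_msc	0.821	0.931	0.928
REC_med	other_msc	0.786	0.913	0.912
ADSC_med	other_msc	0.821	0.917	0.919
iMSC	artificial_msc	0.663	0.859	0.866
FB	non_msc	0.699	0.870	0.882
WP	non_msc	0.720	0.890	0.886
PAEC	non_msc	0.462	0.803	0.810
CD14_monocytes	non_msc	0.132	0.578	0.596
T_cells	non_msc	0.100	0.541	0.592
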