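Site-level sample counts of the multi-site ENIGMA-Anxiety GAD brain-age
study whose statistical structure the synthetic phantom cohort emulates.
train_sites.tsv: the five healthy-control training samples.
test_sites.tsv: the 27 clinical test-set sites (hc_n / gad_n are healthy
controls and generalized-anxiety-disorder cases after quality control;
Pittsburgh-Price contributed GAD cases only).
Used by the test suite to cross-check cohort bookkeeping totals.
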