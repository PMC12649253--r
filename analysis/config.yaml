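# Study configuration for the demo analysis chain (01..06).
# A synthetic four-wave cohort emulating a middle-aged-and-older national
# panel: ~3,916 subjects observed in years 0/2/4/7.
n_subjects: 3916
seed: 11
out_dir: results/demo
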