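# Demo configuration for run_pipeline() / the `pipeline` CLI subcommand.
# Any field of default_config() may appear here; omitted fields keep their
# defaults. Kept small so the end-to-end run finishes in minutes on one CPU.
seed: 1
n_archaea: 6
n_bacteria: 10
archaea_fraction: 0.10
template_len: 1500
genome_len: 5000
# target the universal bacterial cores' Tm so both sets run in one program
target_tm: 46
n_reads: 120
rank: genus
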