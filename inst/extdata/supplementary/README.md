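Drop-in location for the deposited catalogue tables used by the
reproduction checks (see the package README, "Reproducing the results"):

- crossovers.tsv : hybrid_id, chrom, left_marker, right_marker (bp, 1-based)
- coldspots.tsv  : hybrid_id, chrom, start, end (bp, 1-based inclusive)
- genome.tsv     : chromosome <TAB> length (no header)

These are not bundled; export them from the deposited per-hybrid
crossover and coldspot supplementary tables of the source study.
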