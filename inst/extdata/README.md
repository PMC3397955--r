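# extdata

Place the published 154-species survey table (journal supplementary file
`pone.0040861.s006`, a CSV of species, taxonomy, total 454 sequence length,
GC proportion and microsatellite base counts per canonical motif) here as

    pone0040861_s006_dataset_s1.csv

to enable the published-value assertions in the acceptance suite and the
`t3`-`t11` entries of `scripts/acceptance.R`.  The file is not
redistributable with this package; without it those computations are
exercised on a synthetic stand-in survey only.  If the column headers
differ from the defaults, pass `col_map` to `read_profiles_csv()`.
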