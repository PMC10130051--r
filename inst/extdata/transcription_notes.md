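# Fixture provenance notes

The packaged CSVs transcribe the published 27-run study tables (L27 coded
design; lettuce/basil growth, chlorophyll and element means of three
replicates per treatment; confirmation-test report). The typeset tables are
printed without cell delimiters, so a few digit groupings are ambiguous in
plain-text renderings. Resolutions applied here:

- `l27_design.csv`: parsed as run-number followed by six coded digits. The
  parse is cross-checked three ways: it matches the GF(3) linear-combination
  construction (columns a, b, a+b, 2a+b, c, a+c over the base-3 expansion of
  the run index) cell-for-cell, it satisfies strength-2 orthogonality for all
  15 column pairs, and known anchor rows (run 1 = 111111, run 5 = 122222,
  run 10 = 212312, run 27 = 332132) agree.
- `lettuce_growth.csv`, run 1: the digit string `1.820.3211.32` is resolved
  as fresh_root = 1.82, dry_root = 0.321, chlorophyll = 1.32. Three-decimal
  dry-root values occur unambiguously elsewhere (run 2: 0.367), and a
  chlorophyll of 11.3 would be a 3x outlier against the column range
  (1.2-4.25).
- `lettuce_growth.csv`, run 24: `0.5520.32` resolved as dry_leaf = 0.55,
  fresh_root = 2.0, dry_root = 0.32 (fresh_root printed as bare `2`).
- `basil_elements.csv`, run 12, boron: printed as `2a3.80` in the extracted
  text; transcribed as 23.80 (column range 13.8-40.1; the `a` is an OCR
  artifact).
- `confirmation_tests.csv`: the printed error column is reproduced verbatim.
  For most rows 100*|expected - predicted|/expected recomputes the printed
  value at 2 decimals; rows where rounding of the printed expected/predicted
  values breaks self-consistency (e.g. basil dry_leaf: |0.11-0.10|/0.11 =
  9.1% vs printed 2.68; basil Ca: |5.63-3.59|/5.63 = 36% vs printed 0.98)
  are retained as printed but are not computational targets. The
  `selfConsistent` flag computed by `confirmationData()` identifies rows
  whose printed error agrees with its own inputs to +/- 0.01.
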