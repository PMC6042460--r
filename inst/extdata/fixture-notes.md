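# Notes on the bundled printed-table transcriptions

The three coefficient/out-degree fixtures transcribe the printed summary
tables of the source study's report (the study's raw per-patient scores were
distributed only as a non-machine-readable DOCX and are not bundled; the
package's synthetic cohort generator stands in for them).

Files:

- `cihd.csv` — the 46-category ICF core set for chronic ischemic heart
  disease (2 body-structure, 12 body-function, 15 activity/participation,
  17 environmental categories).
- `table2_outdegree.csv` — printed out-degree of each of the 46 categories
  in the published dependency graph.
- `table3_coeffs.csv` — sparse triplets (`response_code,predictor_code,
  coefficient`) of the printed "strong" coefficient table (entries >= 0.75
  plus the small same-row companions the table prints); 25 nonzero cells,
  14 of them >= 0.75.
- `table4_coeffs.csv` — sparse triplets of the printed "weak" coefficient
  table (entries <= 0.25, including the five negative cells); 38 nonzero
  cells.
- `table3_raw.txt`, `table4_raw.txt` — the printed header and row strings
  as extracted (cells run together), kept so every parsed cell is traceable
  to a printed cell. Cell boundaries were resolved under the constraint that
  each row yields exactly one value per printed column (14 for table 3, 16
  for table 4); every such parse was unique, and all values restated in the
  report's prose agree with the transcription.

Known anomalies, kept verbatim rather than repaired:

- The weak-table header contains code `b620`, which does not exist in the
  46-category core set (plausibly a misprint of `d620`). It is kept as
  printed; three cells reference it (d630→0.058, e450→0.016).
- The weak-table header ends with a second occurrence of `s410` (it also
  opens the row labels). The trailing column is kept as a genuine `s410`
  predictor column; three cells reference it (b152→0.020, e125→0.064,
  e580→0.010).
- The report's prose states a minimum out-degree of 2, but the printed
  out-degree table contains d760 = 0 and d870 = 1. The table is transcribed
  verbatim; the contradiction is not resolved.
- The report's prose counts "16 dependence coefficients < 0.25", which does
  not equal the nonzero cell count of the printed weak table (38). The
  transcription keeps the table as printed.
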