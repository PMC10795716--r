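# Bundled validation-study contingency tables

Plain-text tab-separated matrices of the published cross-tabulations from
the Espiro-app validation study (n = 118 spirometries; rows are the app's
calls, columns the pulmonologist's). Load them with
`spirointerp::study_tables()`.

- `table1_pulmonologist1.tsv`, `table1_pulmonologist2.tsv` — dichotomous
  (normal/impaired) pattern calls, app vs each pulmonologist.
- `table3_pulmonologist1.tsv` — four-level pattern calls vs
  pulmonologist 1, who did not distinguish obstructive from mixed; the
  app's mixed calls are folded into the obstructive row (3 x 3).
- `table3_pulmonologist2.tsv` — full four-level pattern calls vs
  pulmonologist 2 (4 x 4).
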