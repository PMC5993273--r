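# Published per-horse reference values for the 44-horse focal cohort
# (laterality index, z statistic, reported p, significance call), used by
# reproduce_study() for its printed-vs-computed comparison. `p_basis`
# records which method the reported p-value agrees with under the
# n <= 25 exact-test rule: "exact", "normal" (rows where the published
# table fell back to the normal approximation despite low n), or "typo"
# (rows matching neither; known misprints).
.table2_printed <- tibble::tribble(
  ~horse_id, ~li, ~z, ~p, ~sig, ~p_basis,
  "A",   42.86,  2.27, 0.023, "S(R)", "normal",
  "B",   55.56,  2.36, 0.031, "S(R)", "exact",
  "C",  -61.91, -2.84, 0.007, "S(L)", "exact",
  "D",   14.29,  0.53, 0.593, "",     "normal",
  "E",   50.00,  1.14, 0.289, "",     "exact",
  "F", -100.00, -2.65, 0.016, "S(L)", "exact",
  "G",  -71.43, -1.89, 0.125, "",     "exact",
  "H",   55.56,  1.67, 0.180, "",     "exact",
  "I",  -41.18, -1.70, 0.090, "",     "normal",
  "J",  -62.50, -2.50, 0.021, "S(L)", "exact",
  "K",  -25.00, -0.71, 0.717, "",     "typo",
  "L",  -35.48, -1.98, 0.048, "S(L)", "normal",
  "M",   16.67,  0.58, 0.564, "",     "normal",
  "N",    0.00,  0.00, 1.000, "",     "exact",
  "O",  -66.67, -2.31, 0.039, "S(L)", "exact",
  "P",   42.86,  1.60, 0.180, "",     "exact",
  "Q",  -15.38, -0.78, 0.433, "",     "normal",
  "R",  -12.50, -0.50, 0.617, "",     "normal",
  "S",   20.00,  0.63, 0.754, "",     "exact",
  "T",   17.65,  0.73, 0.467, "",     "normal",
  "U", -100.00, -2.45, 0.031, "S(L)", "exact",
  "V",    7.69,  0.28, 0.782, "",     "normal",
  "W",   63.64,  2.11, 0.065, "",     "exact",
  "X",   17.65,  0.73, 0.467, "",     "normal",
  "Y",   42.86,  1.60, 0.180, "",     "exact",
  "Z",  -66.67, -1.63, 0.219, "",     "exact",
  "AA",  14.29,  0.53, 0.593, "",     "normal",
  "AB", -33.33, -1.00, 0.508, "",     "exact",
  "AC", -100.00, -2.83, 0.008, "S(L)", "exact",
  "AD", -71.43, -1.89, 0.125, "",     "exact",
  "AE",  55.56,  1.67, 0.180, "",     "exact",
  "AF", -60.00, -1.90, 0.109, "",     "exact",
  "AG",  25.00,  0.71, 0.727, "",     "exact",
  "AH",  -5.26, -0.23, 0.819, "",     "normal",
  "AI",  16.67,  0.58, 0.564, "",     "normal",
  "AJ", -16.67, -0.58, 0.564, "",     "normal",
  "AK", -66.67, -1.63, 0.219, "",     "exact",
  "AL",  42.86,  1.13, 0.453, "",     "exact",
  "AM",  11.11,  0.33, 1.000, "",     "exact",
  "AN",  60.00,  1.34, 0.375, "",     "exact",
  "AO",  42.86,  1.13, 0.453, "",     "exact",
  "AP", -48.94, -3.35, 0.001, "S(L)", "normal",
  "AQ", -33.33, -1.53, 0.127, "",     "normal",
  "AR",  55.56,  1.67, 0.180, "",     "exact"
)

# The one published z value inconsistent with its own lead counts
# (6 R / 2 L gives z = 1.41; a digit transposition).
.printed_z_typos <- "E"
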