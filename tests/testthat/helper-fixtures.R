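# Shared fixtures built once per test run.

# Synthetic stand-in reference set (representatives + homologs) for the
# packaged catalog; seed fixed so anchors and identities are reproducible.
REFS <- synthetic_reference_set(seed = 101)
REF_REPS <- Filter(function(r) !isTRUE(r$synthetic_member), REFS)

ABL <- REFS[["ABL86758"]]
ABL_PROFILE <- build_profile(ABL$sequence, clade_label = "ABL86758")
ABL_CAL <- calibrate_evalues(ABL_PROFILE, n_random = 200, seed = 7)

# Build a planted-homolog benchmark: background proteome plus intact and
# motif-broken copies of the ABL representative, with ground truth.
make_planted_benchmark <- function(n_background = 300, n_intact = 10,
                                   n_broken = 5, identity = 0.6,
                                   seed = 11) {
  bg <- random_proteome(n_background, seed = seed)
  a <- plant_homologs(bg, ABL$sequence, ABL$motifs, n_intact, identity,
                      motif_intact = TRUE, seed = seed + 1,
                      clade_label = "ABL86758", taxon_class = "Bacilli")
  b <- plant_homologs(a$proteins, ABL$sequence, ABL$motifs, n_broken,
                      identity, motif_intact = FALSE, seed = seed + 2,
                      clade_label = "ABL86758", taxon_class = "Bacilli")
  list(proteins = b$proteins, truth = rbind(a$truth, b$truth))
}
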