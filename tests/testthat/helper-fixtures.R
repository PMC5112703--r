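# Hand-designed 20-feature / 57-sample miR matrix exercising both
# preprocessing rules, with every threshold derivable by hand.
#
# Pooled values (1140): 657 zeros, 196 threes, 228 fives, 52 tens,
# 7 twelves. The pooled 10th percentile is 0 and the pooled 90th
# percentile is 5 (position 1026.1 of 1140 falls among the fives);
# the abundance cutoff at n = 57 is floor(0.25 * 57) = 14.
#
#  - rows z1..z5: all zero            -> 0 samples above 0, abundance drop
#  - rows c1..c4: constant 5          -> 57 above, but range 0 <= 5, range drop
#  - rows g1..g7: 28 zeros, 28 threes, one 12
#                                     -> 29 above, range 12 > 5, retained
#  - rows l1..l4: 13 tens, 44 zeros   -> 13 above < 14, abundance drop
make_filter_fixture <- function() {
  n <- 57
  rows <- list()
  for (i in 1:5) rows[[paste0("z", i)]] <- rep(0, n)
  for (i in 1:4) rows[[paste0("c", i)]] <- rep(5, n)
  for (i in 1:7) rows[[paste0("g", i)]] <- c(rep(0, 28), rep(3, 28), 12)
  for (i in 1:4) rows[[paste0("l", i)]] <- c(rep(10, 13), rep(0, 44))
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("S%02d", seq_len(n))
  expression_matrix(m, "miR")
}

filter_fixture_expected <- list(
  retained = paste0("g", 1:7),
  n_dropped_abundance = 9L,
  n_dropped_range = 4L,
  abundance_threshold = 0,
  range_threshold = 5,
  min_samples_above = 14L)

# 40-row association fixture: mi = 1..40 and r = -(1..40)/40, so the MI
# upper 10% tail is rows 37..40 (cutoff between 36 and 37) and the
# Pearson lower 2.5% tail is row 40 alone (cutoff between -1.000 and
# -0.975); the intersection is exactly row 40.
make_selection_fixture <- function() {
  data.frame(mir_id = sprintf("m%02d", 1:40),
             probe_id = sprintf("p%02d", 1:40),
             pearson_r = -(1:40) / 40,
             mi = as.numeric(1:40),
             stringsAsFactors = FALSE)
}

# small simulation shared by pipeline-level tests
small_sim_config <- function(seed = 42L, ...) {
  sim_config(n_samples = 57, n_mirs = 60, n_mrnas = 400, n_true_pairs = 10,
             n_decoys = 800, rng_seed = seed, ...)
}

small_pipeline_config <- function(out_dir, seed = 42L) {
  pipeline_config(list(
    seed = seed, out_dir = out_dir,
    simulate = list(n_samples = 57, n_mirs = 60, n_mrnas = 400,
                    n_true_pairs = 10, n_decoys = 800)))
}
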