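test_that("pearson matches hand-computed values and rejects degeneracy", {
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 2:1), "at least 3")
})

test_that("ksg_mi equals the brute-force reference bitwise", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(20)
    y <- 0.5 * x + rnorm(20)
    got <- ksg_mi(x, y, mi_params(k = 4, noise_amplitude = 0))
    expect_identical(got, ksg_mi_ref(x, y, k = 4))
  }
  # other neighbour counts too
  set.seed(99)
  x <- runif(25); y <- runif(25)
  for (k in c(1, 3, 7))
    expect_identical(ksg_mi(x, y, mi_params(k = k, noise_amplitude = 0)),
                     ksg_mi_ref(x, y, k = k))
})

test_that("ksg_mi is symmetric and validates its inputs", {
  x <- dither(rnorm(40), 1)
  y <- dither(rnorm(40), 2)
  p0 <- mi_params(noise_amplitude = 0)
  expect_identical(ksg_mi(x, y, p0), ksg_mi(y, x, p0))
  expect_error(ksg_mi(x[1:4], y[1:4], mi_params(k = 4)), "N > k")
  expect_error(ksg_mi(rep(1, 40), y, p0), "zero-variance")
  expect_error(ksg_mi(c(x, NA), c(y, 1), p0), "finite")
  expect_error(ksg_mi(x, y[1:10], p0), "equal length")
})

test_that("ksg_mi is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(600)
  y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(600)
  p <- mi_params(rng_seed = 5)
  base <- ksg_mi(x, y, p)
  expect_lt(abs(ksg_mi(exp(x), y, p) - base), 0.05)
  expect_lt(abs(ksg_mi(x, y^3 + 2 * y, p) - base), 0.05)
})

test_that("ksg_mi tracks the Gaussian closed form at one correlation", {
  g <- rbigauss(2000, 0.6, seed = 21)
  mi <- ksg_mi(g$x, g$y, mi_params(rng_seed = 21))
  expect_lt(abs(mi - (-0.5 * log(1 - 0.36))), 0.05)
})

test_that("pairwise_associations enumerates all pairs deterministically", {
  set.seed(8)
  mir <- expression_matrix(matrix(rnorm(2 * 30, 6), 2,
                                  dimnames = list(c("mA", "mB"),
                                                  paste0("S", 1:30))), "miR")
  mrna <- expression_matrix(matrix(rnorm(3 * 30, 8), 3,
                                   dimnames = list(c("p1", "p2", "p3"),
                                                   paste0("S", 1:30))),
                            "mRNA-probe")
  tab <- pairwise_associations(mir, mrna, mi_params(rng_seed = 4))
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$mir_id, rep(c("mA", "mB"), each = 3))
  expect_true(all(tab$pearson_r >= -1 & tab$pearson_r <= 1))
  # deterministic given the seed
  tab2 <- pairwise_associations(mir, mrna, mi_params(rng_seed = 4))
  expect_identical(tab, tab2)
  # sample mismatch is an error
  colnames(mrna) <- rev(colnames(mrna))
  expect_error(pairwise_associations(mir, mrna, mi_params()),
               "identical ordered sample list")
})

test_that("pairwise grid agrees with the single-pair estimator", {
  set.seed(14)
  xm <- matrix(rnorm(3 * 25), 3, dimnames = list(paste0("m", 1:3),
                                                 paste0("S", 1:25)))
  ym <- matrix(rnorm(4 * 25), 4, dimnames = list(paste0("p", 1:4),
                                                 paste0("S", 1:25)))
  # pre-dithered input, package noise stage off
  xm[] <- dither(xm, 31)
  ym[] <- dither(ym, 32)
  tab <- pairwise_associations(expression_matrix(xm, "miR"),
                               expression_matrix(ym, "mRNA-probe"),
                               mi_params(noise_amplitude = 0))
  p0 <- mi_params(noise_amplitude = 0)
  for (r in seq_len(nrow(tab))) {
    expect_equal(tab$mi[r],
                 ksg_mi(xm[tab$mir_id[r], ], ym[tab$probe_id[r], ], p0),
                 tolerance = 1e-12)
    expect_equal(tab$pearson_r[r],
                 pearson(xm[tab$mir_id[r], ], ym[tab$probe_id[r], ]),
                 tolerance = 1e-12)
  }
})

test_that("pairing is invariant under a common sample permutation", {
  set.seed(15)
  xm <- matrix(rnorm(2 * 40), 2, dimnames = list(paste0("m", 1:2),
                                                 paste0("S", 1:40)))
  ym <- matrix(rnorm(2 * 40), 2, dimnames = list(paste0("p", 1:2),
                                                 paste0("S", 1:40)))
  xm[] <- dither(xm, 51)
  ym[] <- dither(ym, 52)
  perm <- sample(40)
  p0 <- mi_params(noise_amplitude = 0)
  a <- pairwise_associations(expression_matrix(xm, "miR"),
                             expression_matrix(ym, "mRNA-probe"), p0)
  b <- pairwise_associations(expression_matrix(xm[, perm], "miR"),
                             expression_matrix(ym[, perm], "mRNA-probe"), p0)
  expect_equal(a$mi, b$mi, tolerance = 1e-12)
  expect_equal(a$pearson_r, b$pearson_r, tolerance = 1e-12)
})

test_that("a planted noise-free pair dominates its row block", {
  cfg <- sim_config(n_mirs = 15, n_mrnas = 60, n_true_pairs = 1,
                    frac_nonlinear = 0, noise_sd = 0,
                    frac_phenotype_linked = 0, frac_zero_mirs = 0.2,
                    slope_range = c(-1, -1), rng_seed = 19)
  p <- simulate_expression_panel(cfg)
  # all-zero miR rows are constant and excluded with a warning
  tab <- suppressWarnings(
    pairwise_associations(p$mir, p$mrna, mi_params(rng_seed = 2)))
  row <- tab[tab$mir_id == p$truth$mir_id & tab$probe_id == p$truth$mrna_id, ]
  expect_equal(row$pearson_r, -1, tolerance = 1e-6)
  block <- tab[tab$mir_id == p$truth$mir_id, ]
  expect_identical(block$probe_id[which.max(block$mi)], p$truth$mrna_id)
})

test_that("constant features are excluded with a warning", {
  xm <- rbind(ok = dither(rnorm(20), 61), flat = rep(2, 20))
  colnames(xm) <- paste0("S", 1:20)
  ym <- matrix(dither(rnorm(20), 62), 1,
               dimnames = list("p1", paste0("S", 1:20)))
  expect_warning(
    tab <- pairwise_associations(expression_matrix(xm, "miR"),
                                 expression_matrix(ym, "mRNA-probe"),
                                 mi_params(noise_amplitude = 0)),
    "constant")
  expect_identical(tab$mir_id, "ok")
})
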