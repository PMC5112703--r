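test_that("hypergeometric tail matches a direct arithmetic case", {
  # urn N = 20 pairs, K = 5 active, draw n = 5, observe all 5 active:
  # p = 1 / C(20, 5)
  expect_equal(mirassoc:::hyper_tail_p(5, 5, 20, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
})

test_that("per-miR enrichment computes counts, fold and exact p", {
  # universe: two miRs over genes G1..G12, all mapped
  universe <- data.frame(
    mir_id = rep(c("mA", "mB"), each = 10),
    probe_id = rep(sprintf("p%02d", 1:10), 2),
    gene_symbol = rep(sprintf("G%02d", 1:10), 2),
    stringsAsFactors = FALSE)
  idmap <- id_map(
    probe_gene = data.frame(probe_id = sprintf("p%02d", 1:10),
                            gene_symbol = sprintf("G%02d", 1:10)),
    family_mir = data.frame(family = c("fA", "fB"),
                            mir_id = c("mA", "mB")))
  # predictions: mA -> G1..G10, mB -> G1..G10 (urn N = 20)
  preds <- list(diana = data.frame(
    mir_key = rep(c("mA", "mB"), each = 10),
    gene_symbol = rep(sprintf("G%02d", 1:10), 2),
    score = 0.9))
  # active: all five of mA's first genes (K = 5, n = 10 per miR)
  putative <- data.frame(mir_id = "mA", probe_id = sprintf("p%02d", 1:5),
                         gene_symbol = sprintf("G%02d", 1:5),
                         stringsAsFactors = FALSE)
  got <- mir_active_enrichment(putative, preds, universe, idmap)
  a <- got[got$mir_id == "mA", ]
  expect_identical(a$n_predicted_in_universe, 10L)
  expect_identical(a$n_active, 5L)
  expect_equal(a$observed_fraction, 0.5)
  expect_equal(a$background_fraction, 5 / 20)
  expect_equal(a$fold_enrichment, 2)
  expect_equal(a$p_hypergeometric, hyper_tail_ref(5, 5, 20, 10),
               tolerance = 1e-12)
  b <- got[got$mir_id == "mB", ]
  expect_identical(b$n_active, 0L)
  expect_equal(b$p_hypergeometric, 1)
})

test_that("a single-miR universe has fold enrichment exactly 1", {
  universe <- data.frame(mir_id = "mA", probe_id = paste0("p", 1:6),
                         gene_symbol = paste0("G", 1:6),
                         stringsAsFactors = FALSE)
  idmap <- id_map(probe_gene = data.frame(probe_id = paste0("p", 1:6),
                                          gene_symbol = paste0("G", 1:6)),
                  family_mir = data.frame(family = "fA", mir_id = "mA"))
  preds <- list(diana = data.frame(mir_key = "mA",
                                   gene_symbol = paste0("G", 1:6),
                                   score = 0.9))
  putative <- data.frame(mir_id = "mA", probe_id = paste0("p", 1:2),
                         gene_symbol = paste0("G", 1:2))
  got <- mir_active_enrichment(putative, preds, universe, idmap)
  expect_equal(got$fold_enrichment, 1)
})

test_that("fold arithmetic: observed 5/10 against background 0.05 is 10x", {
  # 10 miRs x 10 predictions = 100 pairs, 5 active overall, all on mA
  universe <- data.frame(
    mir_id = rep(sprintf("m%02d", 1:10), each = 10),
    probe_id = rep(sprintf("p%02d", 1:10), 10),
    gene_symbol = rep(sprintf("G%02d", 1:10), 10),
    stringsAsFactors = FALSE)
  idmap <- id_map(probe_gene = data.frame(probe_id = sprintf("p%02d", 1:10),
                                          gene_symbol = sprintf("G%02d", 1:10)),
                  family_mir = data.frame(family = sprintf("f%02d", 1:10),
                                          mir_id = sprintf("m%02d", 1:10)))
  preds <- list(diana = data.frame(
    mir_key = rep(sprintf("m%02d", 1:10), each = 10),
    gene_symbol = rep(sprintf("G%02d", 1:10), 10), score = 0.9))
  putative <- data.frame(mir_id = "m01", probe_id = sprintf("p%02d", 1:5),
                         gene_symbol = sprintf("G%02d", 1:5))
  got <- mir_active_enrichment(putative, preds, universe, idmap)
  expect_equal(got$background_fraction[1], 0.05)
  expect_equal(got$fold_enrichment[got$mir_id == "m01"], 10)
  expect_error(mir_active_enrichment(putative, preds, universe[0, ], idmap),
               "empty")
})

test_that("GO categories are selected by substring and size", {
  go <- data.frame(
    term_id = sprintf("GO:%07d", 1:5),
    name = c("epithelial to mesenchymal transition", "pigmentation",
             "Melanin metabolic process", "cell cycle",
             "epithelium development"),
    stringsAsFactors = FALSE)
  go$members <- I(list(paste0("G", 1:40), paste0("G", 1:4),
                       paste0("G", 1:20), paste0("G", 1:50),
                       paste0("G", 1:501)))
  got <- select_go_categories(go)
  # 'pigmentation' has 4 members (< 5) and 'epithelium development' 501
  # (> 500); 'cell cycle' matches no substring
  expect_identical(got$term_id, c("GO:0000001", "GO:0000003"))
  # case-insensitive matching caught "Melanin"
  expect_true("Melanin metabolic process" %in% got$name)
})

test_that("GO target enrichment handles the boundary cases", {
  cats <- data.frame(term_id = "GO:1", name = "pigmentation")
  cats$members <- I(list(paste0("G", 1:10)))
  bg <- paste0("G", 1:100)
  inside <- go_target_enrichment(paste0("G", 1:5), cats, bg)
  expect_equal(inside$fraction_annotated, 1)
  expect_equal(inside$fold, 10)
  outside <- go_target_enrichment(paste0("G", 90:99), cats, bg)
  expect_equal(outside$fraction_annotated, 0)  # G90..G99 not in members
  expect_equal(outside$fold, 0)
  expect_error(go_target_enrichment(character(0), cats, bg), "empty")
  expect_error(go_target_enrichment("NOPE", cats, bg), "subset")
})

test_that("uniformly drawn targets give fold near 1", {
  set.seed(77)
  bg <- sprintf("G%04d", 1:2000)
  cats <- data.frame(term_id = "GO:1", name = "melanosome")
  cats$members <- I(list(sample(bg, 400)))
  folds <- replicate(20, {
    go_target_enrichment(sample(bg, 300), cats, bg)$fold
  })
  expect_lt(abs(mean(folds) - 1), 0.1)
})

test_that("disjoint targets and categories give fraction 0 and fold 0", {
  cats <- data.frame(term_id = "GO:1", name = "pigmentation")
  cats$members <- I(list(character(0)))
  got <- go_target_enrichment(c("A", "B"), cats, c("A", "B", "C"))
  expect_equal(got$fraction_annotated, 0)
  expect_equal(got$fold, 0)
})
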