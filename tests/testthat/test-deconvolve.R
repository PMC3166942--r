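test_that("fold-change marker selection ranks by enrichment and stays disjoint", {
  pure <- rbind(
    strong = c(100, 100, 1, 1, 1, 1),   # A-enriched, fold ~ 100
    weak   = c(10, 10, 1, 1, 1, 1),     # A-enriched, fold ~ 10
    flat   = c(5, 5, 5, 5, 5, 5),       # uniform, fold ~ 1
    bgene  = c(1, 1, 50, 50, 1, 1),     # B-enriched
    cgene  = c(1, 1, 1, 1, 30, 30))     # C-enriched
  colnames(pure) <- paste0("s", 1:6)
  types <- setNames(rep(c("A", "B", "C"), each = 2), colnames(pure))

  w <- capture_warnings(panel <- select_markers(pure, types, n = 2))
  expect_match(w, "fold change", all = FALSE)
  expect_identical(panel$markers$A, c("strong", "weak"))  # descending fold
  expect_identical(panel$markers$B, "bgene")
  expect_identical(panel$markers$C, "cgene")
  expect_false("flat" %in% unlist(panel$markers))
  expect_equal(anyDuplicated(unlist(panel$markers)), 0L)
  expect_true(all(diff(panel$fold_changes$A) <= 0))

  expect_error(select_markers(pure, types, n = 0), "positive")
})

test_that("planted markers are recovered from simulated pure profiles", {
  hits <- tot <- 0
  for (s in 1:20) {
    sim <- simulate_mixture(markers_per_type = 20, seed = 200 + s)
    panel <- select_markers(sim$pure, sim$pure_types, n = 20)
    for (t in names(panel$markers)) {
      planted <- names(sim$markers)[sim$markers == t]
      hits <- hits + length(intersect(panel$markers[[t]], planted))
      tot <- tot + length(planted)
    }
  }
  expect_gte(hits / tot, 0.9)
})

test_that("noise-free mixtures are deconvolved exactly (per-type r = 1)", {
  sim <- simulate_mixture(noise_sd = 0, seed = 31)
  panel <- select_markers(sim$pure, sim$pure_types, n = 50)
  for (s in c("1.max", "3.kMax", "6.Avg")) {
    pred <- predict_proportions(sim$mixtures, panel, strategy = s)
    sc <- score_predictions(pred, sim$truth)
    expect_equal(unname(sc$per_type), rep(1, 4), tolerance = 1e-12,
                 info = s)
    # predicted proportions follow the convention: each type sums to 1
    expect_equal(unname(rowSums(pred)), rep(1, 4))
  }
})

test_that("predictions are invariant to a global intensity rescaling", {
  sim <- simulate_mixture(seed = 32)
  panel <- select_markers(sim$pure, sim$pure_types, n = 30)
  p1 <- predict_proportions(sim$mixtures, panel, strategy = "6.Avg")
  p2 <- predict_proportions(sim$mixtures * 7.5, panel, strategy = "6.Avg")
  expect_equal(p2, p1)
})

test_that("absent markers are dropped with a warning; empty panels fail", {
  sim <- simulate_mixture(seed = 33)
  panel <- select_markers(sim$pure, sim$pure_types, n = 10)
  mix_sub <- sim$mixtures[-match(panel$markers[[1]][1], rownames(sim$mixtures)), ]
  expect_warning(pred <- predict_proportions(mix_sub, panel, "6.Avg"),
                 "absent")
  expect_equal(dim(pred), c(4, 12))
})

test_that("a cell type collapsing to non-positive totals is an error", {
  pure <- rbind(ma = c(10, 1), mb = c(1, 10))
  colnames(pure) <- c("pA", "pB")
  types <- c(pA = "A", pB = "B")
  panel <- select_markers(pure, types, n = 1)
  mix <- rbind(ma = c(-5, -4, -6), mb = c(1, 2, 3))
  colnames(mix) <- paste0("x", 1:3)
  expect_error(predict_proportions(mix, panel, "1.max"), "A")
})

test_that("scoring agrees with its definitions and a permuted null", {
  sim <- simulate_mixture(noise_sd = 0, seed = 34)
  truth <- sim$truth
  expect_equal(score_predictions(truth, truth)$pooled, 1)
  expect_equal(unname(score_predictions(truth, truth)$per_type), rep(1, 4))

  # permuting samples within each type destroys the association on average
  set.seed(99)
  rs <- replicate(100, {
    perm <- truth[, sample(ncol(truth))]
    colnames(perm) <- colnames(truth)
    score_predictions(perm, truth)$pooled
  })
  expect_lt(abs(mean(rs)), 0.1)

  bad <- truth[, 1:6]
  expect_error(score_predictions(bad, truth), "samples")
})

test_that("marker-count sweep produces one row per (count, strategy)", {
  sim <- simulate_mixture(markers_per_type = 15, seed = 35)
  w <- capture_warnings(
    marker_count_sweep(sim$mixtures, sim$pure, sim$pure_types, sim$truth,
                       counts = 400, strategies = "6.Avg"))
  expect_match(w, "fold change", all = FALSE)  # 400 exceeds what qualifies
  suppressWarnings(
    sweep_tab <- marker_count_sweep(sim$mixtures, sim$pure, sim$pure_types,
                                    sim$truth, counts = c(5, 10, 40),
                                    strategies = c("1.max", "6.Avg")))
  expect_equal(nrow(sweep_tab), 6)
  expect_identical(colnames(sweep_tab),
                   c("n_markers", "strategy", "pooled_r", "mean_type_r",
                     "min_type_r"))
  expect_true(all(is.finite(sweep_tab$pooled_r)))
})
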