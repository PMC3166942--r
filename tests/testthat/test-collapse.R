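sample_mat <- function() {
  m <- rbind(p1 = c(5, 6, 7), p2 = c(1, 2, 3), p3 = c(2, 2, 2),
             p4 = c(0, 1, 0), p5 = c(9, 1, 2), p6 = c(4, 4, 4))
  colnames(m) <- paste0("s", 1:3)
  m
}
sample_groups <- c(p1 = "gA", p2 = "gA", p3 = "gA", p4 = "gB", p5 = "gB",
                   p6 = "gC")

test_that("fewest-missing trim keeps exactly the minimum-missing rows", {
  m <- rand_expr(5, 6, seed = 3)
  g <- c(r001 = "G1", r002 = "G1", r003 = "G1", r004 = "G2", r005 = "G2")
  m["r003", 1:2] <- NA          # G1 missing counts {0, 0, 2}
  t1 <- trim_fewest_missing(m, g)
  expect_identical(rownames(t1), c("r001", "r002", "r004", "r005"))

  # complete matrix: identity
  m2 <- rand_expr(4, 3, seed = 4)
  g2 <- setNames(rep("G", 4), rownames(m2))
  expect_identical(trim_fewest_missing(m2, g2), m2)

  # singleton group keeps its only row however incomplete
  m3 <- rbind(a = c(NA, NA, NA, NA, NA, 1))
  colnames(m3) <- paste0("s", 1:6)
  expect_identical(rownames(trim_fewest_missing(m3, c(a = "G"))), "a")
})

test_that("row scores match their definitions", {
  m <- rbind(x = c(1, 2, 3), y = c(-3, 1, NA), z = c(1, 3, 5))
  expect_equal(unname(row_score(m, "MaxMean")), c(2, -1, 3))
  expect_equal(unname(row_score(m, "absMaxMean")[2]), 2)
  # unbiased sample variance, hand-computed: var(1,3,5) = 4
  expect_equal(unname(row_score(m, "maxRowVariance")[3]), 4)
  # fewer than 2 non-missing values: variance undefined
  m2 <- rbind(w = c(7, NA, NA))
  expect_true(is.na(row_score(m2, "maxRowVariance")))
})

test_that("representative selection takes the extreme score with mean then seeded ties", {
  sub <- rbind(p1 = c(5, 5, 5), p2 = c(3, 3, 3))
  colnames(sub) <- paste0("s", 1:3)
  expect_identical(select_representative(sub, "MaxMean"), "p1")
  expect_identical(select_representative(sub, "MinMean"), "p2")

  v <- rbind(p1 = c(0, 1, 2), p2 = c(0, 2, 4))   # variances 1 and 4
  colnames(v) <- paste0("s", 1:3)
  expect_identical(select_representative(v, "maxRowVariance"), "p2")

  # identical rows: random but reproducible under the seed
  tie <- rbind(p1 = c(1, 2, 3), p2 = c(1, 2, 3), p3 = c(1, 2, 3))
  colnames(tie) <- paste0("s", 1:3)
  picks <- vapply(c(0L, 0L, 7L, 7L), function(s)
    select_representative(tie, "MaxMean", seed = s), character(1))
  expect_identical(picks[1], picks[2])
  expect_identical(picks[3], picks[4])

  # a row with undefined variance loses to any row with a defined one
  u <- rbind(p1 = c(9, NA, NA), p2 = c(1, 2, 1))
  colnames(u) <- paste0("s", 1:3)
  expect_identical(select_representative(u, "maxRowVariance"), "p2")
})

test_that("collapse matches brute-force per-group argmax for MaxMean", {
  m <- sample_mat()
  res <- collapse_rows(m, sample_groups, method = "MaxMean")
  expect_identical(rownames(res$matrix), c("gA", "gB", "gC"))
  for (g in names(res$group2row)) {
    ids <- names(sample_groups)[sample_groups == g]
    expected <- oracle_representative_set(m[ids, , drop = FALSE], "MaxMean")
    expect_identical(unname(res$group2row[g]), expected)
    # representative fidelity: output row is a bit-identical copy
    expect_identical(unname(res$matrix[g, ]), unname(m[res$group2row[g], ]))
  }
})

test_that("average collapse equals independent column means per group", {
  m <- sample_mat()
  res <- collapse_rows(m, sample_groups, method = "average")
  for (g in rownames(res$matrix)) {
    ids <- names(sample_groups)[sample_groups == g]
    manual <- apply(m[ids, , drop = FALSE], 2, mean)
    expect_equal(res$matrix[g, ], manual)
  }
  expect_true(all(res$group2row == "<average>"))
})

test_that("singleton groups pass through unchanged under every method", {
  m <- rbind(only = c(1.5, -2, 7)); colnames(m) <- paste0("s", 1:3)
  g <- c(only = "G")
  for (meth in c("MaxMean", "MinMean", "absMaxMean", "absMinMean",
                 "maxRowVariance", "average")) {
    expect_equal(unname(collapse_rows(m, g, method = meth)$matrix["G", ]),
                 unname(m["only", ]), info = meth)
  }
  # ME returns a unit-norm rescaling perfectly correlated with the row
  me <- collapse_rows(m, g, method = "ME")$matrix["G", ]
  expect_equal(unname(cor(me, m["only", ])), 1)
})

test_that("custom aggregation functions are dispatched and validated", {
  m <- sample_mat()
  res <- collapse_rows(m, sample_groups, method = "function",
                       method_function = function(x) apply(x, 2, max))
  expect_equal(unname(res$matrix["gA", ]), c(5, 6, 7))
  expect_true(all(res$group2row == "<function>"))

  expect_error(collapse_rows(m, sample_groups, method = "function"),
               "method_function")
  expect_error(collapse_rows(m, sample_groups, method = "MaxMean",
                             method_function = identity), "method_function")
  expect_error(collapse_rows(m, sample_groups, method = "function",
                             method_function = function(x) 1), "gA")
})

test_that("unmapped and blank-group rows are dropped with a message", {
  m <- sample_mat()
  g <- c(p1 = "gA", p2 = "gA", p3 = "", p4 = "gB")   # p3 blank, p5/p6 absent
  expect_message(res <- collapse_rows(m, g), "3 row")
  expect_identical(rownames(res$matrix), c("gA", "gB"))
})

test_that("connectivity-based dispatch: >= 3 rows use the hub, 2 fall back, 1 passes", {
  set.seed(42)
  s <- rnorm(12)
  m <- rbind(h = (c(rnorm(12, sd = 0.1)) + s),     # close to shared signal
             a = s + rnorm(12, sd = 0.8),
             b = s + rnorm(12, sd = 0.8),
             x = c(5, 6, 4, 5, 6, 4, 5, 6, 4, 5, 6, 4),
             y = c(1, 1, 2, 1, 1, 2, 1, 1, 2, 1, 1, 2),
             z = rnorm(12))
  colnames(m) <- paste0("s", 1:12)
  g <- c(h = "G3", a = "G3", b = "G3", x = "G2", y = "G2", z = "G1")
  res <- collapse_rows(m, g, method = "MaxMean", connectivity_based = TRUE)
  # 3-row group: independently computed hub
  expect_identical(unname(res$group2row["G3"]),
                   oracle_hub(m[c("h", "a", "b"), ]))
  # 2-row group: falls back to MaxMean
  expect_identical(unname(res$group2row["G2"]), "x")
  # singleton passes through
  expect_identical(unname(res$group2row["G1"]), "z")
})

test_that("a hub that carries the shared signal of its group is selected", {
  # h tracks the mean of two weakly related signals; its pairwise
  # correlations dominate, which the hand-rolled adjacency oracle confirms
  set.seed(7)
  u <- rnorm(20); v <- rnorm(20)
  m <- rbind(r1 = u, r2 = v, h = (u + v) / 2 + rnorm(20, sd = 0.05))
  colnames(m) <- paste0("s", 1:20)
  expect_identical(oracle_hub(m), "h")
  res <- collapse_rows(m, c(r1 = "G", r2 = "G", h = "G"),
                       connectivity_based = TRUE)
  expect_identical(unname(res$group2row["G"]), "h")
})

test_that("collapse is invariant to input row order (no-tie data)", {
  m <- rand_expr(12, 6, miss_frac = 0.1, seed = 9)
  g <- setNames(rep(c("G1", "G2", "G3"), each = 4), rownames(m))
  ref <- collapse_rows(m, g, method = "MaxMean")
  for (s in 1:3) {
    set.seed(100 + s)
    perm <- sample(nrow(m))
    shuffled <- collapse_rows(m[perm, ], g, method = "MaxMean")
    expect_identical(shuffled$group2row, ref$group2row)
    expect_equal(shuffled$matrix, ref$matrix)
  }
})

test_that("module eigengene is unit-norm, sign-oriented and dominant", {
  # identical rows: perfectly correlated with the common profile
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3)); colnames(m) <- paste0("s", 1:3)
  me <- module_eigengene(m)
  expect_equal(sum(me^2), 1)
  expect_equal(unname(cor(me, c(1, 2, 3))), 1)

  # x and -x: one PC explains everything; orientation rule fixes the sign
  x <- c(2, -1, 3, 0)
  m2 <- rbind(p = x, q = -x); colnames(m2) <- paste0("s", 1:4)
  me2 <- module_eigengene(m2)
  expect_equal(me2, module_eigengene(m2[c(2, 1), ]))  # deterministic
  expect_equal(abs(unname(cor(me2, x))), 1)

  # variance explained >= any single standardized row's direction
  m3 <- rand_expr(5, 10, seed = 21)
  std <- t(scale(t(m3)))
  me3 <- module_eigengene(m3)
  v_me <- sum((std %*% me3)^2)
  for (i in seq_len(nrow(std))) {
    u <- std[i, ] / sqrt(sum(std[i, ]^2))
    expect_gte(v_me, sum((std %*% u)^2) - 1e-10)
  }

  # all-constant group: warn and return zeros
  m4 <- rbind(a = rep(2, 4), b = rep(5, 4)); colnames(m4) <- paste0("s", 1:4)
  expect_warning(z <- module_eigengene(m4), "constant")
  expect_equal(unname(z), rep(0, 4))
})

test_that("strategy presets map to the documented method configurations", {
  expect_identical(strategy_config("1.max"),
                   list(method = "MaxMean", connectivity_based = FALSE))
  expect_identical(strategy_config("4.kVar"),
                   list(method = "maxRowVariance", connectivity_based = TRUE))
  expect_identical(strategy_config("5.ME")$method, "ME")
  expect_identical(strategy_config("6.Avg")$method, "average")
  expect_error(strategy_config("7.bogus"), "1\\.max")
})

test_that("one output row per retained group, labelled by group", {
  for (s in 1:5) {
    m <- rand_expr(20, 8, miss_frac = 0.15, seed = 30 + s)
    g <- setNames(sample(paste0("G", 1:6), 20, replace = TRUE), rownames(m))
    res <- collapse_rows(m, g, method = "absMaxMean")
    expect_identical(rownames(res$matrix), sort(unique(unname(g))))
    expect_identical(names(res$group2row), rownames(res$matrix))
  }
})
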