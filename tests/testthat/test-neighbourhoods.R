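# Spatial graph, hop-shell aggregation, FMI, GMM stability selection,
# CN enrichment / proximity, covariate correlation.

test_that("Delaunay spatial graph trims long edges and has no self-loops", {
  withr::with_seed(1, {
    cells <- data.frame(x_um = runif(80, 0, 200), y_um = runif(80, 0, 200))
    g <- build_spatial_graph(cells, max_edge_um = 30)
    el <- igraph::as_edgelist(g)
    expect_true(all(el[, 1] != el[, 2]))
    len <- sqrt((cells$x_um[el[, 1]] - cells$x_um[el[, 2]])^2 +
                (cells$y_um[el[, 1]] - cells$y_um[el[, 2]])^2)
    expect_true(all(len <= 30))
  })
})

test_that("hop aggregation: L = 0 identity, path-graph hand check, empty shells zero", {
  cells <- data.frame(x_um = c(0, 10, 20), y_um = 0,
                      m1 = c(1, 2, 4), m2 = c(0, 1, 0))
  g <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  f0 <- aggregate_features(cells, g, L = 0, markers = c("m1", "m2"))
  expect_equal(unname(f0[, 1:2]), unname(as.matrix(cells[, c("m1", "m2")])))
  f1 <- aggregate_features(cells, g, L = 1, markers = c("m1", "m2"))
  expect_equal(unname(f1[2, 3:4]), c(mean(c(1, 4)), mean(c(0, 0))))
  expect_equal(unname(f1[1, 3:4]), c(2, 1))
  # disconnected singleton with L = 2: all shells empty -> zero-padded
  g2 <- igraph::make_empty_graph(3, directed = FALSE)
  f2 <- aggregate_features(cells, g2, L = 2, markers = c("m1", "m2"))
  expect_true(all(f2[, 3:6] == 0))
  expect_equal(attr(f2, "n_empty_shells"), 6L)
})

test_that("FMI matches the pair-counting oracle on random labelings of <= 8 items", {
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 3)),
               oracle_fmi(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 3)))
  withr::with_seed(3, {
    for (i in 1:200) {
      n <- sample(2:8, 1)
      a <- sample.int(3, n, replace = TRUE)
      b <- sample.int(3, n, replace = TRUE)
      expect_equal(fowlkes_mallows(a, b), oracle_fmi(a, b), tolerance = 1e-12)
    }
  })
  # relabelling invariance and identity
  a <- c(1, 1, 2, 3, 3, 2)
  expect_equal(fowlkes_mallows(a, a), 1)
  expect_equal(fowlkes_mallows(a, c(9, 9, 4, 7, 7, 4)), 1)
  expect_error(fowlkes_mallows(1, 1), "2 items")
  expect_error(fowlkes_mallows(c(1, 2), 1), "equal length")
})

test_that("stability selection recovers planted K and is deterministic", {
  withr::with_seed(5, {
    d <- 6
    X <- rbind(matrix(rnorm(240), ncol = 2),
               matrix(rnorm(240, mean = rep(c(d, 0), each = 120)), ncol = 2),
               matrix(rnorm(240, mean = rep(c(d / 2, d * sqrt(3) / 2), each = 120)),
                      ncol = 2))
    sc <- select_k(X, 2:5, R = 6, seed = 11)
    expect_equal(sc$best_k, 3)
    expect_gte(mclust::adjustedRandIndex(sc$labels, rep(1:3, each = 120)), 0.9)
    sc2 <- select_k(X, 2:5, R = 6, seed = 11)
    expect_identical(sc$labels, sc2$labels)
    expect_identical(sc$stability, sc2$stability)
    # duplicating every point leaves K* unchanged
    sc3 <- select_k(rbind(X, X), 2:5, R = 6, seed = 11)
    expect_equal(sc3$best_k, 3)
    expect_error(select_k(X, 2:5, R = 1), "R >= 2")
    expect_error(select_k(X, c(2, 500), R = 2), "k_range")
  })
})

test_that("between-K stability mode runs and returns a valid curve", {
  withr::with_seed(6, {
    X <- rbind(matrix(rnorm(200), ncol = 2),
               matrix(rnorm(200, 5), ncol = 2))
    sc <- select_k(X, 2:4, R = 4, seed = 2, mode = "between")
    expect_true(all(sc$stability >= 0 & sc$stability <= 1))
    expect_true(sc$best_k %in% 2:4)
  })
})

test_that("CN enrichment equals the contingency-table oracle and averages to 1", {
  cn <- rep(c("cn1", "cn2"), c(40, 60))
  pop <- c(rep(c("X", "Y"), c(30, 10)), rep(c("X", "Y"), c(20, 40)))
  enr <- cn_enrichment(cn, pop)
  # oracle by hand: overall X = 0.5, Y = 0.5
  expect_equal(enr["cn1", "X"], (30 / 40) / 0.5)
  expect_equal(enr["cn1", "Y"], (10 / 40) / 0.5)
  expect_equal(enr["cn2", "Y"], (40 / 60) / 0.5)
  # row-weighted average over types of enrichment x overall fraction = 1
  overall <- prop.table(table(pop))
  for (r in rownames(enr))
    expect_equal(sum(enr[r, ] * as.numeric(overall[colnames(enr)])), 1)
  # absent type -> 0
  cn2 <- c("a", "a", "b", "b")
  pop2 <- c("X", "X", "Y", "Y")
  expect_equal(cn_enrichment(cn2, pop2)["a", "Y"], 0)
})

test_that("CN proximity: null labels score near zero, segregated CNs score on the diagonal", {
  withr::with_seed(7, {
    cells <- data.frame(x_um = runif(300, 0, 300), y_um = runif(300, 0, 300))
    g <- build_spatial_graph(cells, max_edge_um = 40)
    # null: labels random -> |z| < 3 nearly everywhere
    lab_null <- sample(paste0("cn", 1:3), 300, replace = TRUE)
    pn <- cn_proximity(list(lab_null), list(g), n_perm = 150, seed = 1)
    expect_gte(mean(abs(pn$score) < 3), 0.99)
    # segregated: left half cn1, right half cn2 -> positive diagonal,
    # negative off-diagonal
    lab_seg <- ifelse(cells$x_um < 150, "cn1", "cn2")
    psg <- cn_proximity(list(lab_seg), list(g), n_perm = 150, seed = 1)
    expect_gt(psg$score["cn1", "cn1"], 3)
    expect_gt(psg$score["cn2", "cn2"], 3)
    expect_lt(psg$score["cn1", "cn2"], -3)
    # single CN -> 1x1 zero score by convention
    p1 <- cn_proximity(list(rep("cn1", 300)), list(g), n_perm = 10, seed = 1)
    expect_equal(unname(p1$score[1, 1]), 0)
  })
})

test_that("covariate correlation gates between Pearson and Spearman correctly", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1, 6.0)
  ct <- correlate_with_covariate(x, y)
  expect_equal(ct$method, "pearson")
  # closed-form Pearson oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$estimate, r_oracle, tolerance = 1e-12)
  # y = x exactly: r = 1, p at the floor
  ct2 <- correlate_with_covariate(x, x + 0)
  expect_equal(ct2$estimate, 1)
  expect_lt(ct2$p_value, 1e-6)
  # heavy-tailed covariate triggers the Spearman branch
  withr::with_seed(9, {
    hx <- rnorm(12)
    hy <- exp(rnorm(12, 0, 2.5))^2
    taken <- correlate_with_covariate(hx, hy)
    expect_equal(taken$method, "spearman")
  })
  expect_error(correlate_with_covariate(rep(1, 6), x), "variance")
  expect_error(correlate_with_covariate(1:3, 1:3), "4 cases")
})
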