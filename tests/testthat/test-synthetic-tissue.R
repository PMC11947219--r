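# Synthetic tissue generator: determinism, placement laws, expression counts,
# mask perturbation.

simple_spec <- function(placement = "CSR", density = 100, seed = 1L,
                        pp = list(), vessels = list(), planted = list()) {
  tissue_spec(populations = list(
    population_spec("A", "Myeloid", density,
                    c(m1 = 5, m2 = 0.2), placement = placement,
                    placement_params = pp)),
    vessels = vessels, planted_pairs = planted, seed = seed)
}

test_that("identical spec and seed give byte-identical output", {
  sp <- vs_tissue_spec("AntoniA", seed = 11, scale = 0.1)
  expect_identical(generate_roi(sp, "r", "c"), generate_roi(sp, "r", "c"))
  sp2 <- vs_tissue_spec("AntoniA", seed = 12, scale = 0.1)
  expect_false(identical(generate_roi(sp, "r", "c"),
                         generate_roi(sp2, "r", "c")))
})

test_that("CSR population has Poisson counts at the stated intensity and passes a quadrat test", {
  withr::with_seed(21, {
    counts <- vapply(1:100, function(i)
      nrow(generate_roi(simple_spec(density = 100, seed = i))), 0)
    # mean and variance both ~ lambda under Poisson
    expect_gt(mean(counts), 85)
    expect_lt(mean(counts), 115)
    expect_gt(var(counts) / mean(counts), 0.6)
    expect_lt(var(counts) / mean(counts), 1.6)
    # chi-square quadrat CSR test at alpha = 0.05 passes in >= 90/100 seeds
    pvals <- vapply(1:100, function(i) {
      cells <- generate_roi(simple_spec(density = 300, seed = 1000 + i))
      q <- table(factor(floor(cells$x_um / 200), 0:4),
                 factor(floor(cells$y_um / 200), 0:4))
      suppressWarnings(stats::chisq.test(as.vector(q))$p.value)
    }, 0)
    expect_gte(sum(pvals > 0.05), 90)
  })
})

test_that("zero populations give an empty table with valid schema", {
  sp <- tissue_spec(populations = list(), seed = 1)
  out <- generate_roi(sp)
  expect_equal(nrow(out), 0)
  expect_true(all(c("cell_id", "roi_id", "case_id", "x_um", "y_um",
                    "region", "population", "parent_group") %in% colnames(out)))
})

test_that("Thomas-cluster nearest-neighbour distances are stochastically smaller than CSR", {
  # empirical NN-distance CDFs over 60 paired seeds at matched intensity
  nn_med <- function(cells) {
    d <- as.matrix(stats::dist(cbind(cells$x_um, cells$y_um)))
    diag(d) <- Inf
    stats::median(apply(d, 1, min))
  }
  withr::with_seed(31, {
    med_thomas <- vapply(1:60, function(i) {
      cells <- generate_roi(simple_spec("ThomasCluster", density = 200, seed = i,
                                        pp = list(mean_offspring = 20, sigma_um = 20)))
      nn_med(cells)
    }, 0)
    med_csr <- vapply(1:60, function(i) {
      cells <- generate_roi(simple_spec("CSR", density = 200, seed = 500 + i))
      nn_med(cells)
    }, 0)
    # clustered medians sit well below CSR medians as distributions
    expect_lt(stats::ks.test(med_thomas, med_csr, alternative = "greater")$p.value, 0.01)
    expect_lt(mean(med_thomas), mean(med_csr))
  })
})

test_that("perivascular cells lie within the vessel halo", {
  v <- vessel_spec(cbind(c(100, 500, 900), c(500, 500, 500)), halo_radius_um = 30)
  cells <- generate_roi(simple_spec("Perivascular", density = 300, seed = 5,
                                    vessels = list(v)))
  # distance to the horizontal segment y = 500, x in [100, 900]
  dx <- pmax(100 - cells$x_um, 0, cells$x_um - 900)
  d <- sqrt(dx^2 + (cells$y_um - 500)^2)
  expect_gte(mean(d <= 30 + 1e-9), 0.95)
})

test_that("batch effects multiply marker intensities per case", {
  be <- list(caseA = c(m1 = 2, m2 = 1), caseB = c(m1 = 0.5, m2 = 1))
  sp <- tissue_spec(populations = list(
    population_spec("A", "Myeloid", 300, c(m1 = 5, m2 = 1), dispersion = 0.05)),
    batch_effects = be, seed = 3)
  a <- generate_roi(sp, "r", "caseA")
  b <- generate_roi(sp, "r", "caseB")
  expect_gt(mean(a$m1), 3 * mean(b$m1) / 1.2)  # ratio ~ 4 up to noise
  expect_equal(mean(a$m2) / mean(b$m2), 1, tolerance = 0.1)
})

test_that("expression counts: schema, planted folds, and error contracts", {
  pairs <- data.frame(pair_id = "p1", ligand = "LG", receptor = "RC",
                      sender = "S", receiver = "R", fold = 8)
  gen <- generate_expression_counts(c("S", "R"), pairs, n_cells_per_pop = 150,
                                    seed = 2)
  expect_equal(ncol(gen$counts), 300)
  expect_true(all(c("LG", "RC") %in% rownames(gen$counts)))
  expect_gt(mean(gen$counts["LG", gen$labels == "S"]),
            4 * mean(gen$counts["LG", gen$labels == "R"]))
  expect_gt(mean(gen$counts["RC", gen$labels == "R"]),
            4 * mean(gen$counts["RC", gen$labels == "S"]))
  # fold <= 0 rejected
  bad <- pairs; bad$fold <- 0
  expect_error(generate_expression_counts(c("S", "R"), bad), "fold")
  # unknown population rejected
  bad2 <- pairs; bad2$sender <- "nope"
  expect_error(generate_expression_counts(c("S", "R"), bad2), "unknown")
  # empty: n_cells_per_pop = 0
  gen0 <- generate_expression_counts(c("S", "R"), pairs, n_cells_per_pop = 0)
  expect_equal(ncol(gen0$counts), 0)
  expect_equal(nrow(gen0$counts), length(gen0$genes))
})

test_that("mask perturbation: identity at 0, vanishing flagged, labels preserved", {
  mask <- matrix(0L, 40, 40)
  mask <- paint_square(mask, 5, 5, 10, 1L)
  mask <- paint_square(mask, 25, 25, 3, 2L)
  expect_identical(unclass(generate_mask_pair(mask, 0))[seq_along(mask)],
                   mask[seq_along(mask)])
  out <- generate_mask_pair(mask, 2, seed = 7)
  expect_true(all(setdiff(unique(as.vector(out)), 0L) %in% c(1L, 2L)))
  # perturbation larger than the small object's radius can erase it; over many
  # seeds the 3x3 object vanishes at least once and is flagged when it does
  vanished_any <- any(vapply(1:20, function(s) {
    o <- generate_mask_pair(mask, 3, seed = s)
    2L %in% attr(o, "vanished") || !(2L %in% as.vector(o))
  }, TRUE))
  expect_true(vanished_any)
})

test_that("rendered discs carry the planted signal", {
  cells <- data.frame(cell_id = 1:2, roi_id = "r", case_id = "c",
                      x_um = c(10, 30), y_um = c(10, 30),
                      region = "AntoniA", population = "A",
                      parent_group = "Myeloid", m1 = c(4, 7))
  rend <- generate_channel_stack(cells, 40, 40, cell_radius_um = 3)
  disc_area <- sum(rend$mask == 1L)
  expect_equal(sum(rend$stack[, , "m1"][rend$mask == 1L]), 4 * disc_area)
  # empty table -> zero stack and mask
  rend0 <- generate_channel_stack(cells[0, ], 20, 20, markers = "m1")
  expect_true(all(rend0$stack == 0) && all(rend0$mask == 0L))
})
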