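mk_ld_g <- function(dosages, pos = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(dosages, data.frame(chrom = "Chr01", pos = pos,
                                      ref = "A", alt = "G"))
}

test_that("pairwise r2 matches hand computation and honours symmetry", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  y <- c(0, 1, 1, 2, 0, 2, 1, 0)
  g <- mk_ld_g(cbind(x, y))
  ld <- pairwise_r2(g, n_perm = 500, min_complete = 5, seed = 2)
  expect_equal(ld$pairs$r2, cor(x, y)^2, tolerance = 1e-12)
  expect_lt(ld$pairs$p, 0.2)              # correlated pair

  # identical vectors: r2 = 1, permutation P at the floor
  g2 <- mk_ld_g(cbind(x, x))
  ld2 <- pairwise_r2(g2, n_perm = 200, min_complete = 5, seed = 2)
  expect_equal(ld2$pairs$r2, 1)

  # allele relabelling at one site leaves r2 unchanged
  g3 <- mk_ld_g(cbind(x, 2 - y))
  ld3 <- pairwise_r2(g3, n_perm = 0, min_complete = 5)
  expect_equal(ld3$pairs$r2, cor(x, y)^2, tolerance = 1e-12)
})

test_that("independent sites give small r2 and near-uniform permutation P", {
  set.seed(6)
  n <- 300
  g <- mk_ld_g(cbind(rbinom(n, 2, 0.4), rbinom(n, 2, 0.4)))
  ld <- pairwise_r2(g, n_perm = 1000, seed = 3)
  expect_lt(ld$pairs$r2, 0.03)
  expect_gt(ld$pairs$p, 0.01)
})

test_that("block detection finds runs and splits at unlinked interruptions", {
  set.seed(11)
  base <- rbinom(60, 2, 0.5)
  noise <- function() rbinom(60, 2, 0.5)
  # sites 1-3 identical (perfect LD), site 4 unlinked, sites 5-6 identical
  g <- mk_ld_g(cbind(base, base, base, noise(), b5 <- rbinom(60, 2, 0.5),
                     b5))
  ld <- pairwise_r2(g, n_perm = 1000, seed = 4)
  bl <- detect_blocks(ld, r2_min = 0.75, p_max = 1e-2)
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$n_sites, c(3L, 2L))
  expect_equal(bl$start[1], 99L)          # bp span of the first block
  expect_equal(bl$end[1], 300L)

  # adding an unlinked site never merges blocks (idempotence of the rule)
  bl2 <- detect_blocks(ld, r2_min = 0.75, p_max = 1e-2)
  expect_identical(bl, bl2)
})

test_that("Hill-Weir decay fit recovers rho and reports the 0.2 crossing", {
  set.seed(12)
  d <- exp(runif(400, log(20), log(60000)))
  rho <- 0.0015; n <- 200
  r2 <- pmin(pmax(hill_weir_r2(d, rho, n) + rnorm(400, 0, 0.03), 0), 1)
  fit <- fit_decay(data.frame(dist = d, r2 = r2), n = n)
  expect_lt(abs(fit$rho - rho) / rho, 0.10)
  expect_equal(hill_weir_r2(fit$decay_dist, fit$rho, n), 0.2,
               tolerance = 1e-6)

  # saturated LD never crosses the target within the data range
  suppressWarnings({
    flat <- fit_decay(data.frame(dist = seq(100, 10000, length.out = 60),
                                 r2 = rep(0.98, 60)), n = 100)
  })
  expect_true(is.na(flat$decay_dist))
  expect_match(flat$decay_note, "beyond data range")
})

test_that("simulated copying haplotypes keep high LD local", {
  sim <- simulate_panel(panel_config(sizes = c(S = 80L, NW = 60L, NE = 60L),
                                     n_regions = 1L, region_length = 30000L,
                                     snps_per_region = 300L,
                                     n_founder_haps = 4L, missing_rate = 0,
                                     seed = 13))
  g <- sim$genotypes
  keep <- g$subpop == "S"                  # within one founder pool
  gs <- genotype_matrix(g$dosage[keep, ], g$sites, g$subpop[keep])
  ld <- pairwise_r2(gs, n_perm = 0)
  near <- ld$pairs$r2[ld$pairs$dist < 1500]
  far <- ld$pairs$r2[ld$pairs$dist > 10000]
  expect_gt(length(near), 20)
  expect_gt(mean(near), mean(far) + 0.1)   # LD decays with distance
})
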