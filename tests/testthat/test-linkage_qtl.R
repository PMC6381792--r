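test_that("scan at a fully informative marker equals single-marker regression", {
  set.seed(7)
  n <- 120
  calls <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
                  dimnames = list(sprintf("p%03d", 1:n), c("m1", "m2", "m3")))
  y <- 0.8 * calls[, 2] + rnorm(n)
  dat <- toy_linkage(calls, c(0, 10, 20), y)
  scan <- interval_scan(dat, "V", "T01", threshold = 1)
  at_m2 <- scan$grid$cm == 10
  r2 <- cor(calls[, 2], y)^2
  lod_closed <- -(n / 2) * log10(1 - r2)
  expect_equal(scan$grid$lod[at_m2], lod_closed, tolerance = 1e-8)
  expect_equal(scan$grid$pve[at_m2], 1 - 10^(-2 * lod_closed / n),
               tolerance = 1e-8)
})

test_that("LOD is invariant to affine phenotype transformation and is zero
           for constant phenotypes", {
  set.seed(8)
  n <- 100
  calls <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                  dimnames = list(NULL, paste0("m", 1:4)))
  y <- calls[, 3] + rnorm(n)
  dat1 <- toy_linkage(calls, c(0, 4, 9, 15), y)
  dat2 <- toy_linkage(calls, c(0, 4, 9, 15), 3 - 5 * y)
  s1 <- interval_scan(dat1, "V", "T01")
  s2 <- interval_scan(dat2, "V", "T01")
  expect_equal(s1$grid$lod, s2$grid$lod, tolerance = 1e-10)

  dat3 <- toy_linkage(calls, c(0, 4, 9, 15), rep(2.5, n))
  s3 <- interval_scan(dat3, "V", "T01")
  expect_true(all(s3$grid$lod[!is.na(s3$grid$lod)] == 0))
})

test_that("permutation thresholds are seeded, monotone in alpha, and hit the
           quantile edges", {
  fam <- simulate_fullsib(family_config(n_progeny = 150L, n_lg = 3L,
                                        markers_per_lg = 10L, seed = 13))
  t1 <- permutation_threshold(fam, "V", "T01", n_perm = 200, seed = 5)
  t2 <- permutation_threshold(fam, "V", "T01", n_perm = 200, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_strict <- permutation_threshold(fam, "V", "T01", n_perm = 200,
                                    alpha = 0.01, seed = 5)
  t_loose <- permutation_threshold(fam, "V", "T01", n_perm = 200,
                                   alpha = 0.20, seed = 5)
  expect_gte(as.numeric(t_strict), as.numeric(t1))
  expect_gte(as.numeric(t1), as.numeric(t_loose))
  t_all <- permutation_threshold(fam, "V", "T01", n_perm = 200, alpha = 1,
                                 seed = 5)
  expect_equal(as.numeric(t_all), min(attr(t_all, "max_lods")))
  expect_warning(permutation_threshold(fam, "V", "T01", n_perm = 50),
                 "unstable")
})

test_that("support intervals are symmetric for symmetric profiles and
           one-sided at LG ends", {
  grid <- data.frame(lg = "LG01", cm = 0:20,
                     lod = 6 - abs(0:20 - 10) * 0.5)
  scan <- structure(list(grid = grid), class = "qtl_scan")
  # the drop region is [8, 12]; endpoints expand one grid step outward
  ci <- support_interval(scan, "LG01", 10)
  expect_equal(ci, c(7, 13))
  grid2 <- data.frame(lg = "LG01", cm = 0:20, lod = 6 - (0:20) * 0.5)
  scan2 <- structure(list(grid = grid2), class = "qtl_scan")
  expect_equal(support_interval(scan2, "LG01", 0), c(0, 3))
})

test_that("co-localisation clustering needs both interval overlap and close
           peaks", {
  q <- data.frame(lg = "LG01", peak_cm = c(10, 10.5), lod = 5, pve = 0.1,
                  ci_lo = c(8, 9), ci_hi = c(12, 13),
                  trait = c("V", "BD"), timepoint = "T01")
  expect_equal(nrow(cluster_colocalized(q)), 1L)
  q2 <- q
  q2$peak_cm <- c(10, 11.5)              # overlapping intervals, far peaks
  expect_equal(nrow(cluster_colocalized(q2)), 2L)
  empty <- q[0, ]
  expect_equal(nrow(cluster_colocalized(empty)), 0L)
})

test_that("hotspot permutation test flags concentration but not sparse sets", {
  lens <- c(LG01 = 40, LG02 = 40)
  q <- data.frame(lg = c(rep("LG01", 30), rep("LG02", 10)),
                  peak_cm = c(rep(5.5, 30), runif(10, 0, 40)))
  hs <- hotspot_test(q, lens, n_perm = 300, seed = 3)
  hit <- hs$bins[hs$bins$hotspot, ]
  expect_true(any(hit$lg == "LG01" & hit$cm_lo == 5))
  expect_equal(nrow(hotspot_test(q[0, ], lens)$bins[
    hotspot_test(q[0, ], lens)$bins$hotspot, ]), 0L)
  one <- hotspot_test(q[1, , drop = FALSE], lens, n_perm = 100)
  expect_false(any(one$bins$hotspot))
})

test_that("MQM separates linked QTN and reduces to the plain scan under the
           null", {
  hits <- 0L
  for (s in 1:8) {
    fam <- simulate_fullsib(
      family_config(n_progeny = 400L, n_lg = 3L, markers_per_lg = 25L,
                    missing_rate = 0, seed = 500 + s),
      list(qtn_spec("V", 0.15, "level", lg = "LG01", cm = 10),
           qtn_spec("V", 0.15, "level", lg = "LG01", cm = 40)))
    mq <- mqm_scan(fam, "V", "T06")
    near <- function(x) any(abs(mq$qtl$peak_cm - x) <= 6 &
                              mq$qtl$lg == "LG01")
    if (nrow(mq$qtl) >= 2 && near(10) && near(40)) hits <- hits + 1L
  }
  expect_gte(hits, 6L)                    # both peaks recovered most runs

  fam0 <- simulate_fullsib(family_config(n_progeny = 150L, n_lg = 3L,
                                         markers_per_lg = 10L, seed = 77))
  mq0 <- mqm_scan(fam0, "H", "T01", threshold = 6)   # nothing can exceed 6
  s0 <- interval_scan(fam0, "H", "T01", threshold = 6)
  expect_length(mq0$cofactors, 0L)
  expect_equal(mq0$grid$lod, s0$grid$lod)
  expect_true(mq0$converged)
})

test_that("a strong single QTN converges in at most two cofactor rounds and
           its support interval covers the truth", {
  fam <- simulate_fullsib(
    family_config(n_progeny = 400L, n_lg = 5L, markers_per_lg = 20L,
                  seed = 61),
    list(qtn_spec("V", 0.25, "level", lg = "LG02", cm = 18)))
  mq <- mqm_scan(fam, "V", "T03")
  expect_lte(mq$iterations, 2L)
  pk <- mq$qtl[mq$qtl$lg == "LG02", ][1, ]
  expect_true(pk$ci_lo <= 18 && pk$ci_hi >= 18)
})
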