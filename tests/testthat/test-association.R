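test_that("modified-Bonferroni thresholds follow 1/n and 0.05/n", {
  th <- compute_thresholds(52949)
  expect_equal(signif(th$suggestive, 2), 1.9e-5)
  expect_equal(signif(th$significant, 2), 9.4e-7)
  th1 <- compute_thresholds(1)
  expect_equal(th1$suggestive, 1)
  expect_equal(th1$significant, 0.05)
  expect_lt(th$significant, th$suggestive)
})

test_that("IBS kinship is symmetric, 1 for duplicates, and separates
           subpopulations", {
  set.seed(3)
  dos <- matrix(rbinom(20 * 150, 2, 0.4), 20, 150)
  dos[2, ] <- dos[1, ]                     # duplicate individuals
  g <- genotype_matrix(dos, data.frame(chrom = "c", pos = 1:150 * 10,
                                       ref = "A", alt = "G"))
  K <- estimate_kinship(g)
  expect_equal(unclass(K)[1, 2], 1)
  expect_identical(unclass(K), t(unclass(K)))
  expect_true(all(diag(unclass(K)) == 1))

  sim <- simulate_panel(panel_config(sizes = c(A = 40L, B = 40L), f = 0.2,
                                     missing_rate = 0, seed = 14))
  K2 <- unclass(suppressWarnings(estimate_kinship(sim$genotypes)))
  sp <- sim$genotypes$subpop
  within <- mean(K2[sp == "A", sp == "A"][upper.tri(diag(40))])
  between <- mean(K2[sp == "A", sp == "B"])
  expect_gt(within, between)
})

test_that("with identity kinship and no covariates the MLM equals OLS", {
  set.seed(15)
  n <- 80; m <- 25
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  g <- genotype_matrix(dos, data.frame(chrom = "c", pos = 1:m * 10,
                                       ref = "A", alt = "G"))
  y <- rnorm(n) + 0.4 * dos[, 5]
  ph <- data.frame(individual = rownames(g$dosage), trait = "V",
                   timepoint = "T1", value = y)
  K <- diag(n)
  dimnames(K) <- list(rownames(g$dosage), rownames(g$dosage))
  rec <- mlm_scan(g, ph, "V", "T1", K = K, Q = NULL)
  p_ols <- vapply(seq_len(m), function(j) {
    ct <- summary(lm(y ~ dos[, j]))$coefficients
    # Wald chi-square on the same z statistic as the scan
    z <- ct[2, 3]
    pchisq(z^2, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(rec$p, p_ols, tolerance = 1e-6)
})

test_that("permuted phenotypes give uniform P-values and planted SNPs are
           found", {
  sim <- simulate_panel(panel_config(missing_rate = 0, seed = 16),
                        qtns = list(qtn_spec("V", 0.15, "level",
                                             min_maf = 0.3)))
  g <- sim$genotypes
  K <- suppressWarnings(estimate_kinship(g))
  set.seed(1)
  ph <- sim$phenotypes
  ix <- ph$trait == "V" & ph$timepoint == "T3"
  ph$value[ix] <- sample(ph$value[ix])     # break genotype-phenotype link
  rec0 <- mlm_scan(g, ph, "V", "T3", K = K)
  ks <- suppressWarnings(ks.test(rec0$p[!is.na(rec0$p)], "punif"))
  expect_gt(ks$p.value, 0.01)

  rec1 <- mlm_scan(g, sim$phenotypes, "V", "T3", K = K)
  expect_lt(rec1$p[sim$truth$qtns[[1]]$site], 1e-4)
})

test_that("effect classification reads additive and dominant class-mean
           patterns", {
  set.seed(17)
  n3 <- 40
  x <- rep(c(0, 1, 2), each = n3)
  g <- genotype_matrix(matrix(x, ncol = 1),
                       data.frame(chrom = "c", pos = 1L, ref = "A",
                                  alt = "G"))
  mk_ph <- function(mu) data.frame(individual = rownames(g$dosage),
                                   trait = "V", timepoint = "T1",
                                   value = mu[x + 1] + rnorm(3 * n3, 0, 0.5))
  ce_add <- classify_effect(g, mk_ph(c(10, 15, 20)), "V", "T1", 1, Q = NULL)
  expect_equal(ce_add$class, "additive")
  expect_equal(ce_add$a, 5, tolerance = 0.3)
  expect_equal(ce_add$d, 0, tolerance = 0.3)

  ce_dom <- classify_effect(g, mk_ph(c(10, 20, 10)), "V", "T1", 1, Q = NULL)
  expect_equal(ce_dom$class, "dominant")
  expect_equal(ce_dom$a, 0, tolerance = 0.3)
  expect_equal(ce_dom$d, 10, tolerance = 0.3)

  # swapping which homozygote is "AA" flips the sign of a, leaves d alone
  gswap <- genotype_matrix(matrix(2 - x, ncol = 1), g$sites)
  ph <- mk_ph(c(10, 15, 20))
  ce_sw <- classify_effect(gswap, ph, "V", "T1", 1, Q = NULL)
  ce_or <- classify_effect(g, ph, "V", "T1", 1, Q = NULL)
  expect_equal(ce_sw$a, -ce_or$a, tolerance = 1e-8)
  expect_equal(ce_sw$d, ce_or$d, tolerance = 1e-8)
})

test_that("simulated additive+dominance effects are recovered within 2 SE", {
  sim <- simulate_panel(panel_config(sizes = c(S = 120L, NW = 80L,
                                               NE = 100L),
                                     missing_rate = 0, seed = 18),
                        qtns = list(qtn_spec("BD", 0.15, "level",
                                             dom_ratio = 0.5,
                                             min_maf = 0.35)))
  tr <- sim$truth$effects
  site <- sim$truth$qtns[[1]]$site
  a_true <- tr$effect[tr$timepoint == "T3" & tr$kind == "additive"]
  d_true <- tr$effect[tr$timepoint == "T3" & tr$kind == "dominance"]
  ce <- classify_effect(sim$genotypes, sim$phenotypes, "BD", "T3", site)
  n <- nrow(sim$genotypes$dosage)
  se_rough <- 2 / sqrt(n)                  # conservative contrast SE scale
  expect_lt(abs(ce$a - a_true), 2 * 3 * se_rough)
  expect_lt(abs(ce$d - d_true), 2 * 3 * se_rough)
  expect_true(ce$class %in% c("additive", "both"))
})

test_that("PVE trajectories classify by half-slope rules", {
  expect_equal(classify_trajectory(rep(0.1, 9)), "level")
  expect_equal(classify_trajectory(seq(0.02, 0.2, length.out = 9)),
               "increasing")
  expect_equal(classify_trajectory(seq(0.2, 0.02, length.out = 9)),
               "decreasing")
  expect_equal(classify_trajectory(c(0.02, 0.3)), "unclassified")
  # ramp-then-plateau from the simulator's trajectory class, with noise
  hits <- 0L
  set.seed(19)
  for (r in 1:20) {
    pve <- linkLD:::pve_trajectory(0.2, "increase-then-level", 10) +
      rnorm(10, 0, 0.004)
    if (classify_trajectory(pve) == "increase-then-level") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("hotspot features need repeated association across phenotype sets", {
  set.seed(20)
  sets <- expand.grid(trait = c("H", "BD", "V"),
                      timepoint = paste0("T", 1:9),
                      stringsAsFactors = FALSE)
  # feature fA: SNP associated in 20 sets; fB: 1 set; background noise
  rec <- rbind(
    data.frame(id = "snpA", trait = sets$trait[1:20],
               timepoint = sets$timepoint[1:20], p = 1e-8),
    data.frame(id = "snpB", trait = "H", timepoint = "T1", p = 1e-8),
    data.frame(id = sprintf("n%02d", 1:30),
               trait = sample(sets$trait, 30, TRUE),
               timepoint = sample(sets$timepoint, 30, TRUE), p = 1e-6))
  fmap <- data.frame(id = c("snpA", "snpB", sprintf("n%02d", 1:30)),
                     feature = c("fA", "fB", sprintf("g%02d", 1:30)))
  hs <- find_hotspot_features(rec, fmap, threshold = 1e-4, k_min = 12,
                              n_perm = 300, seed = 2)
  expect_true(hs$hotspot[hs$feature == "fA"])
  expect_false(hs$hotspot[hs$feature == "fB"])
  empty <- find_hotspot_features(rec[0, ], fmap, threshold = 1e-4)
  expect_equal(nrow(empty), 0L)
})

test_that("lead-SNP clustering absorbs linked signals and breaks ties by
           position", {
  set.seed(21)
  n <- 100
  base <- rbinom(n, 2, 0.5)
  dos <- cbind(base, base, rbinom(n, 2, 0.5))
  g <- genotype_matrix(dos, data.frame(chrom = "Chr01",
                                       pos = c(100L, 200L, 5000L),
                                       ref = "A", alt = "G"))
  rec <- data.frame(id = g$sites$id, chrom = "Chr01",
                    pos = g$sites$pos, p = c(1e-8, 1e-6, 1e-7))
  cl <- lead_snp_clusters(rec, g, threshold = 1e-5)
  expect_equal(nrow(cl), 2L)               # perfect-LD pair collapses
  expect_equal(cl$lead[1], g$sites$id[1])  # lower P wins the lead
  expect_equal(cl$n_members[1], 2L)

  rec2 <- rec
  rec2$p <- c(1e-7, 1e-7, 1e-7)            # tie: smaller coordinate leads
  cl2 <- lead_snp_clusters(rec2, g, threshold = 1e-5)
  expect_equal(cl2$lead[1], g$sites$id[1])
})
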