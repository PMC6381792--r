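test_that("recombination between adjacent markers follows the Haldane map", {
  fam <- simulate_fullsib(family_config(n_progeny = 1500L, n_lg = 4L,
                                        markers_per_lg = 12L,
                                        missing_rate = 0, seed = 2))
  # pooled observed-vs-expected recombinant fraction over all adjacent pairs
  obs <- exp_ <- w <- c()
  for (l in unique(fam$map$lg)) {
    mk <- fam$map[fam$map$lg == l, ]
    G <- fam$calls[, mk$marker]
    for (k in seq_len(nrow(mk) - 1)) {
      r_exp <- haldane_r(mk$cm[k + 1] - mk$cm[k])
      r_obs <- mean(G[, k] != G[, k + 1])
      obs <- c(obs, r_obs); exp_ <- c(exp_, r_exp)
    }
  }
  # 2.3 cM corresponds to r = (1 - exp(-2*0.023))/2 ~ 0.0225
  expect_equal(haldane_r(2.3), 0.02248, tolerance = 1e-3)
  expect_lt(abs(mean(obs - exp_)), 0.005)
  expect_gt(cor(obs, exp_), 0.9)
})

test_that("simulators are bit-identical under a fixed seed", {
  a <- simulate_fullsib(family_config(n_progeny = 50L, n_lg = 2L,
                                      markers_per_lg = 8L, seed = 11))
  b <- simulate_fullsib(family_config(n_progeny = 50L, n_lg = 2L,
                                      markers_per_lg = 8L, seed = 11))
  expect_identical(a$calls, b$calls)
  expect_identical(a$phenotypes, b$phenotypes)

  cfgp <- panel_config(sizes = c(S = 20L, NW = 12L, NE = 10L),
                       n_regions = 2L, snps_per_region = 60L, seed = 12)
  pa <- simulate_panel(cfgp)
  pb <- simulate_panel(cfgp)
  expect_identical(pa$genotypes$dosage, pb$genotypes$dosage)
  expect_identical(pa$phenotypes, pb$phenotypes)

  g1 <- simulate_gene_models(3, 30000, seed = 4)
  g2 <- simulate_gene_models(3, 30000, seed = 4)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$seq, g2$seq)
})

test_that("subpopulation differentiation scales with the Balding-Nichols F", {
  win_fst <- function(f, seed) {
    sim <- simulate_panel(panel_config(sizes = c(A = 80L, B = 80L), f = f,
                                       n_regions = 2L,
                                       snps_per_region = 500L,
                                       missing_rate = 0, seed = seed))
    st <- weir_cockerham_fst(sim$genotypes,
                             tile_windows(sim$truth$regions, 500L),
                             "A", "B")
    mean(st$fst, na.rm = TRUE)
  }
  expect_lt(abs(win_fst(0.01, 21)), 0.03)         # F -> 0: differentiation -> 0
  expect_gt(win_fst(0.25, 22), 0.15)
})

test_that("a planted additive QTN explains approximately its target PVE", {
  sim <- simulate_panel(panel_config(sizes = c(S = 150L, NW = 100L,
                                               NE = 120L),
                                     missing_rate = 0, seed = 31),
                        qtns = list(qtn_spec("V", 0.2, "level",
                                             min_maf = 0.3)))
  site <- sim$truth$qtns[[1]]$site
  y <- phenotype_vector(sim$phenotypes, "V", "T3",
                        individuals = rownames(sim$genotypes$dosage))
  r2 <- summary(lm(y ~ sim$genotypes$dosage[, site]))$r.squared
  expect_lt(abs(r2 - 0.2), 0.05)
})

test_that("a planted sweep removes diversity inside its interval only", {
  reg <- data.frame(chrom = "Chr01", start = 0L, end = 40000L, name = "R1")
  sw <- sweep_spec("Chr01", 0L, 15000L, "NW", rho_sweep = 0.05)
  sim <- simulate_panel(panel_config(sizes = c(S = 60L, NW = 60L),
                                     snps_per_region = 1500L,
                                     missing_rate = 0, seed = 41),
                        sweeps = list(sw), regions = reg)
  wd_obj <- window_diversity(sim$genotypes, tile_windows(reg, 1000L), "NW")
  wd_ref <- window_diversity(sim$genotypes, tile_windows(reg, 1000L), "S")
  inside <- wd_obj$end <= 15000
  ratio_in <- sum(wd_obj$pi[inside]) / sum(wd_ref$pi[inside])
  ratio_out <- sum(wd_obj$pi[!inside]) / sum(wd_ref$pi[!inside])
  expect_lt(ratio_in, 0.3)
  expect_gt(ratio_out, 0.6)
  expect_lt(ratio_out, 1.5)
})

test_that("toy gene models are disjoint, frame-consistent and deterministic", {
  gm <- simulate_gene_models(5, 50000, seed = 6)
  expect_equal(nrow(gm$genes), 5L)
  o <- order(gm$genes$start)
  expect_true(all(gm$genes$start[o][-1] >= gm$genes$end[o][-5]))
  cds_len <- tapply(gm$cds$end - gm$cds$start, gm$cds$gene_id, sum)
  expect_true(all(cds_len %% 3 == 0))

  # GFF3 round trip preserves the structure
  f <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_gene_models(gm, f, fa)
  back <- read_gene_models(f, fa)
  expect_equal(sort(back$genes$gene_id), sort(gm$genes$gene_id))
  expect_equal(back$genes[order(back$genes$start),
                          c("start", "end", "strand")],
               gm$genes[order(gm$genes$start), c("start", "end", "strand")],
               ignore_attr = TRUE)
  expect_identical(unname(back$seq), unname(gm$seq))
  expect_equal(nrow(back$ncrna), nrow(gm$ncrna))
})

test_that("epistatic planting yields an interaction without marginal effects", {
  sim <- simulate_panel(panel_config(sizes = c(S = 120L, NW = 90L,
                                               NE = 90L),
                                     missing_rate = 0, seed = 51),
                        epi_pairs = list(epi_spec(NA, NA, "H", 0.15, "dxd",
                                                  min_maf = 0.3)))
  ep <- sim$truth$epi_pairs[[1]]
  g <- sim$genotypes
  y <- phenotype_vector(sim$phenotypes, "H", "T3",
                        individuals = rownames(g$dosage))
  r2a <- summary(lm(y ~ g$dosage[, ep$siteA]))$r.squared
  r2b <- summary(lm(y ~ g$dosage[, ep$siteB]))$r.squared
  expect_lt(r2a, 0.05)                    # near-zero marginal association
  expect_lt(r2b, 0.05)
  rec <- two_locus_partition(g, sim$phenotypes, "H", "T3",
                             ep$siteA, ep$siteB)
  expect_lt(rec$p_int, 0.001)
})
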