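test_that("per-site and per-window pi match direct formulas and brute force", {
  # one site, alt count 1 among n = 4 haplotypes, 250-bp window
  g1 <- toy_from_haplotypes(matrix(c(1, 0), 2, 1), matrix(0, 2, 1),
                            pos = 100L)
  wd <- window_diversity(g1, data.frame(chrom = "Chr01", start = 0L,
                                        end = 250L))
  expect_equal(wd$pi, 2 * 1 * 3 / (4 * 3) / 250)
  expect_equal(wd$S, 1)

  # no segregating sites
  g0 <- toy_from_haplotypes(matrix(1, 3, 2), matrix(1, 3, 2))
  wd0 <- window_diversity(g0, data.frame(chrom = "Chr01", start = 0L,
                                         end = 250L))
  expect_equal(wd0$pi, 0)
  expect_equal(wd0$theta_w, 0)
  expect_equal(wd0$S, 0)

  # brute-force pairwise Hamming oracle on random phased toys
  for (s in 1:5) {
    set.seed(s)
    h1 <- matrix(rbinom(6 * 12, 1, 0.4), 6, 12)
    h2 <- matrix(rbinom(6 * 12, 1, 0.4), 6, 12)
    g <- toy_from_haplotypes(h1, h2, pos = seq_len(12) * 5L)
    wd <- window_diversity(g, data.frame(chrom = "Chr01", start = 0L,
                                         end = 100L))
    expect_equal(wd$pi_total, brute_pi_total(rbind(h1, h2)),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches the hand-computed worked example", {
  # haplotypes 0000, 1000, 1100, 1110: S = 3, mean pairwise diff = 10/6
  expect_lt(abs(tajimas_d(3, 4, 10 / 6) - 0.168), 0.001)
  # pi exactly S/a1 zeroes the numerator
  a1 <- sum(1 / 1:3)
  expect_equal(tajimas_d(3, 4, 3 / a1), 0)
  # undefined, not zero, when S = 0
  expect_true(is.na(tajimas_d(0, 4, 0)))
  # the full path reproduces it from genotypes
  haps <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0))
  g <- toy_from_haplotypes(haps[c(1, 3), ], haps[c(2, 4), ],
                           pos = c(10L, 20L, 30L, 40L))
  wd <- window_diversity(g, data.frame(chrom = "Chr01", start = 0L,
                                       end = 250L))
  expect_lt(abs(wd$tajima_d - 0.168), 0.001)
})

test_that("Weir-Cockerham Fst hits the fixed-difference and oracle values", {
  win <- data.frame(chrom = "Chr01", start = 0L, end = 250L)
  # fixed alternative alleles, no heterozygotes -> Fst = 1
  gfix <- toy_two_pop_site(c(10, 0, 0), c(0, 0, 10))
  expect_equal(weir_cockerham_fst(gfix, win, "P1", "P2")$fst, 1)

  # identical genotype counts -> numerator <= 0, reported raw and flagged
  gsame <- toy_two_pop_site(c(6, 8, 6), c(6, 8, 6))
  fs <- weir_cockerham_fst(gsame, win, "P1", "P2")
  expect_lte(fs$fst, 0)
  expect_true(fs$negative)

  # printed toy counts vs the independent single-site script
  gtoy <- toy_two_pop_site(c(15, 10, 5), c(5, 10, 15))
  expect_equal(weir_cockerham_fst(gtoy, win, "P1", "P2")$fst,
               wc_oracle_site(15, 10, 5, 5, 10, 15), tolerance = 1e-12)
})

test_that("ROD follows its definition and degenerate cases", {
  expect_equal(rod_statistic(0.004, 0.004), 0)
  expect_equal(rod_statistic(0, 0.004), 1)
  expect_equal(rod_statistic(0.001, 0.004), 0.75)
  expect_true(is.na(rod_statistic(0.001, 0)))
})

test_that("joint outliers require the conjunction of both top tails", {
  set.seed(4)
  n <- 300
  stats <- data.frame(chrom = "Chr01", start = (0:(n - 1)) * 250L,
                      end = (1:n) * 250L,
                      fst = rnorm(n, 0.1, 0.02),
                      log_ratio = rnorm(n, 0, 0.5),
                      d_obj = rnorm(n), d_ref = rnorm(n),
                      objective = "NW", reference = "S")
  stats$fst[1] <- 0.9                      # top in Fst only
  fl <- joint_outlier_windows(stats, q = 0.01)
  expect_false(fl$outlier[1])
  both <- which.max(stats$log_ratio)
  stats$fst[both] <- 0.95
  fl2 <- joint_outlier_windows(stats, q = 0.01)
  expect_true(fl2$outlier[both])
  fl_all <- joint_outlier_windows(stats, q = 1)
  expect_true(all(fl_all$outlier))
})

test_that("flagged windows merge by gap rule into selective regions", {
  mk <- function(starts, flag) {
    data.frame(chrom = "Chr01", start = starts, end = starts + 250L,
               fst = 0.5, log_ratio = 1, outlier = flag,
               d_obj = -1, d_ref = 0, objective = "NW", reference = "S")
  }
  st <- mk(seq(0, 2250, by = 250), rep(FALSE, 10))
  st$outlier[2:4] <- TRUE
  r <- merge_regions(st)
  expect_equal(nrow(r), 1L)
  expect_equal(r$end - r$start, 750L)
  expect_equal(r$n_windows, 3L)

  st2 <- mk(seq(0, 2250, by = 250), rep(FALSE, 10))
  st2$outlier[c(2, 5)] <- TRUE             # two unflagged windows between
  expect_equal(nrow(merge_regions(st2, max_gap = 1)), 2L)

  st3 <- mk(seq(0, 2250, by = 250), rep(FALSE, 10))
  st3$outlier[7] <- TRUE
  r3 <- merge_regions(st3)
  expect_equal(r3$end - r3$start, 250L)    # single window = 250 bp region
})

test_that("Tajima confirmation demands lower objective D and enough windows", {
  st <- data.frame(chrom = "Chr01", start = seq(0, 1750, 250),
                   end = seq(250, 2000, 250),
                   d_obj = rep(-2, 8), d_ref = rep(0.5, 8),
                   fst = 0.5, log_ratio = 1, outlier = TRUE,
                   objective = "NW", reference = "S")
  reg <- merge_regions(st)
  conf <- confirm_with_tajima(reg, st)
  expect_true(conf$confirmed)
  # identical distributions are never confirmed
  st$d_obj <- st$d_ref
  conf2 <- confirm_with_tajima(reg, st)
  expect_false(conf2$confirmed)
  # all-monomorphic objective: D undefined, region not evaluable
  st$d_obj <- NA_real_
  conf3 <- confirm_with_tajima(reg, st)
  expect_false(conf3$evaluable)
})

test_that("fixation classes follow the MAF rules per subpopulation", {
  mk_g <- function(mafs) {
    # 25 individuals per subpop; heterozygote count set so the allele
    # frequency equals the requested MAF (50 alleles per subpop)
    dos <- do.call(rbind, lapply(mafs, function(p) {
      k <- round(50 * p)
      matrix(c(rep(1L, k), rep(0L, 25 - k)), ncol = 1)
    }))
    genotype_matrix(dos, data.frame(chrom = "c", pos = 1L, ref = "A",
                                    alt = "G"),
                    subpop = rep(c("S", "NW", "NE"), each = 25))
  }
  expect_equal(classify_fixation(mk_g(c(0.30, 0.02, 0.20)))$class,
               "nearly_fixed")
  expect_equal(classify_fixation(mk_g(c(0.30, 0.00, 0.20)))$class,
               "completely_fixed")
  expect_equal(classify_fixation(mk_g(c(0.30, 0.10, 0.20)))$class,
               "segregating")
})

test_that("window statistics are invariant to individual order and allele
           relabelling", {
  set.seed(9)
  h1 <- matrix(rbinom(10 * 20, 1, 0.3), 10, 20)
  h2 <- matrix(rbinom(10 * 20, 1, 0.3), 10, 20)
  sp <- stats::setNames(rep(c("A", "B"), each = 5), paste0("ind", 1:10))
  g <- toy_from_haplotypes(h1, h2, pos = seq_len(20) * 10L, subpop = sp)
  win <- data.frame(chrom = "Chr01", start = 0L, end = 250L)
  st <- window_stats(g, win, "A", "B")

  # relabel ref/alt (dosage 2 - d)
  gflip <- g
  gflip$dosage <- 2L - g$dosage
  stf <- window_stats(gflip, win, "A", "B")
  expect_equal(st$pi_obj, stf$pi_obj)
  expect_equal(st$theta_obj, stf$theta_obj)
  expect_equal(st$fst, stf$fst)
  expect_equal(st$d_obj, stf$d_obj)

  # permute individuals
  perm <- sample(10)
  gp <- genotype_matrix(g$dosage[perm, ], g$sites, g$subpop[perm])
  stp <- window_stats(gp, win, "A", "B")
  expect_equal(st$pi_obj, stp$pi_obj)
  expect_equal(st$fst, stp$fst)
})
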