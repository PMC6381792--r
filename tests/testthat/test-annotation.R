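test_that("SNPs classify by codon effect, flank distance and ncRNA overlap", {
  gm <- toy_gene_models()
  # gplus CDS covers [110,119): ATG GGA TAA (+ strand)
  sites <- data.frame(
    chrom = "Chr01",
    pos = c(116L,   # GGA -> GGG third codon position: synonymous
            114L,   # GGA -> AGA first position: nonsynonymous
            105L,   # 5'UTR: genic noncoding
            540L,   # > 2 kb from nothing here (region small) - see below
            313L,   # minus strand, first base of GGG codon: nonsynonymous
            311L),  # minus strand, third base of GGG codon: synonymous
    ref = c("A", "G", "T", "T", "C", "C"),
    alt = c("G", "A", "A", "A", "T", "T"))
  set.seed(1)
  g <- genotype_matrix(matrix(rbinom(4 * 6, 2, 0.4), 4, 6), sites)
  ann <- annotate_snps(g, gm, flank_bp = 50L)
  expect_equal(ann$class[1], "synonymous")
  expect_equal(ann$class[2], "nonsynonymous")
  expect_equal(ann$class[3], "genic_noncoding")
  expect_equal(ann$class[4], "intergenic")
  expect_true(ann$ncrna[4])               # inside the lncRNA record
  expect_equal(ann$class[5], "nonsynonymous")
  expect_equal(ann$class[6], "synonymous")

  # with a 2-kb flank the whole toy region becomes genic
  ann2 <- annotate_snps(g, gm, flank_bp = 2000L)
  expect_equal(ann2$class[4], "genic_noncoding")

  # deterministic and order-independent
  perm <- c(3, 1, 6, 2, 5, 4)
  gp <- genotype_matrix(g$dosage[, perm], g$sites[perm, ])
  annp <- annotate_snps(gp, gm, flank_bp = 50L)
  expect_equal(annp$class, ann$class[perm])
})

test_that("per-class diversity recovers a constructed piN/piS ratio", {
  gm <- toy_gene_models()
  # plant SNPs: 1 synonymous site and 1 nonsynonymous site in gplus with
  # allele frequencies chosen so per-site pi differs by ~3x, then verify the
  # ratio of per-bp diversities against the construction
  n <- 40
  mkdos <- function(p) rbinom(n, 2, p)
  set.seed(2)
  sites <- data.frame(chrom = "Chr01", pos = c(116L, 114L),
                      ref = c("A", "G"), alt = c("G", "A"))
  dos <- cbind(mkdos(0.5), mkdos(0.09))
  g <- genotype_matrix(dos, sites)
  ann <- annotate_snps(g, gm, flank_bp = 50L)
  dv <- diversity_by_class(g, ann, gm, flank_bp = 50L)
  bc <- dv$by_class
  pi_syn <- bc$pi_total[bc$class == "synonymous"]
  pi_non <- bc$pi_total[bc$class == "nonsynonymous"]
  # expected per-site pi from realized frequencies (2n haplotypes)
  exp_pi <- function(j) {
    cc <- sum(dos[, j]); nn <- 2 * n
    2 * cc * (nn - cc) / (nn * (nn - 1))
  }
  expect_equal(pi_syn, exp_pi(1), tolerance = 1e-12)
  expect_equal(pi_non, exp_pi(2), tolerance = 1e-12)
  # the reported dn/ds is the ratio of per-potential-site diversities
  syn_bp <- bc$footprint_bp[bc$class == "synonymous"]
  non_bp <- bc$footprint_bp[bc$class == "nonsynonymous"]
  expect_equal(dv$ratios[["dn_ds"]],
               (pi_non / non_bp) / (pi_syn / syn_bp), tolerance = 1e-12)
  expect_gt(syn_bp, 0)
  expect_gt(non_bp, syn_bp)               # nonsyn sites outnumber syn sites
})

test_that("ratios are undefined when a class is empty", {
  gm <- toy_gene_models()
  sites <- data.frame(chrom = "Chr01", pos = 105L, ref = "T", alt = "A")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), sites)
  ann <- annotate_snps(g, gm, flank_bp = 50L)
  dv <- diversity_by_class(g, ann, gm, flank_bp = 50L)
  expect_true(is.na(dv$ratios[["dn_ds"]]))
})
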