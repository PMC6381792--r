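# Shared fixtures and independent oracles. Oracles are deliberately written
# from the primary definitions (not by calling package internals) so they
# stay independent of the code paths they check.

# small genotype matrix from explicit haplotypes: dosage = h1 + h2
toy_from_haplotypes <- function(h1, h2, chrom = "Chr01",
                                pos = NULL, subpop = NULL) {
  stopifnot(dim(h1) == dim(h2))
  dos <- h1 + h2
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 10L
  genotype_matrix(dos,
                  data.frame(chrom = chrom, pos = pos,
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  subpop = subpop)
}

# brute-force mean pairwise Hamming distance over all haplotype pairs,
# summed over sites (the pairwise-difference definition of pi)
brute_pi_total <- function(haps) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(haps[i, ] != haps[j, ])
  tot / choose(n, 2)
}

# independent single-site Weir & Cockerham (1984) theta for two populations,
# written directly from the genotype-count algebra of the original paper
wc_oracle_site <- function(nAA1, nAa1, naa1, nAA2, nAa2, naa2) {
  n1 <- nAA1 + nAa1 + naa1
  n2 <- nAA2 + nAa2 + naa2
  p1 <- (2 * nAA1 + nAa1) / (2 * n1)
  p2 <- (2 * nAA2 + nAa2) / (2 * n2)
  h1 <- nAa1 / n1
  h2 <- nAa2 / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# genotype matrix with two explicit subpopulations built from genotype counts
# at a single site
toy_two_pop_site <- function(counts1, counts2) {
  d1 <- rep(c(2, 1, 0), counts1)       # counts given as (AA, Aa, aa)
  d2 <- rep(c(2, 1, 0), counts2)
  dos <- matrix(c(d1, d2), ncol = 1)
  genotype_matrix(dos,
                  data.frame(chrom = "Chr01", pos = 100L, ref = "A",
                             alt = "G", stringsAsFactors = FALSE),
                  subpop = stats::setNames(rep(c("P1", "P2"),
                                               c(length(d1), length(d2))),
                                           paste0("ind", seq_along(dos))))
}

# hand-built linkage dataset: one LG, markers at given cM, all progeny calls
# and a single phenotype set
toy_linkage <- function(calls, cm, y, trait = "V", timepoint = "T01",
                        lg = "LG01") {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("p%03d", seq_len(nrow(calls)))
  map <- data.frame(lg = lg, marker = colnames(calls), cm = cm,
                    stringsAsFactors = FALSE)
  ph <- data.frame(individual = rownames(calls), trait = trait,
                   timepoint = timepoint, value = y,
                   stringsAsFactors = FALSE)
  linkage_dataset(map, calls, ph)
}

# minimal hand-designed gene model set with a known sequence, one gene per
# strand, and one ncRNA; coordinates 0-based half-open
toy_gene_models <- function() {
  # plus-strand gene: UTR5 [100,110), CDS [110,119), UTR3 [119,130)
  # CDS sequence (positions 110..118): ATG GGA TAA -> M G *
  # minus-strand gene: span [300,340), CDS [310,319); genomic CCC ACG CAT
  # reverse-complements to ATG CGT GGG -> M R G
  n <- 600L
  seqv <- rep("T", n)
  seqv[111:119] <- c("A", "T", "G", "G", "G", "A", "T", "A", "A")
  seqv[311:319] <- c("C", "C", "C", "A", "C", "G", "C", "A", "T")
  genes <- data.frame(gene_id = c("gplus", "gminus"), chrom = "Chr01",
                      start = c(100L, 300L), end = c(130L, 340L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gplus", "gminus"),
                      start = c(100L, 300L), end = c(130L, 340L),
                      stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = c("gplus", "gminus"),
                    start = c(110L, 310L), end = c(119L, 319L),
                    frame = c(0L, 0L), stringsAsFactors = FALSE)
  ncrna <- data.frame(id = "nc1", chrom = "Chr01", start = 520L, end = 560L,
                      class = "lncRNA", stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, cds = cds, ncrna = ncrna,
                 seq = stats::setNames(paste(seqv, collapse = ""), "Chr01"),
                 chrom = "Chr01", region_length = n),
            class = "gene_model_set")
}

# genotype matrix with sites at given 1-based positions and HWE dosages
toy_sites_at <- function(pos, ref, alt, n_ind = 12, p = 0.4, seed = 1) {
  set.seed(seed)
  dos <- matrix(stats::rbinom(n_ind * length(pos), 2, p), n_ind)
  genotype_matrix(dos, data.frame(chrom = "Chr01", pos = pos, ref = ref,
                                  alt = alt, stringsAsFactors = FALSE))
}

# trimmed pipeline configuration for fast end-to-end runs
test_pipeline_config <- function(seed, out_dir) {
  cfg <- pipeline_config(seed = seed, out_dir = out_dir)
  cfg$family$n_progeny <- 200L
  cfg$family$n_lg <- 6L
  cfg$family$markers_per_lg <- 12L
  cfg$family$n_timepoints <- 4L
  cfg$family_qtns <- list(
    list(trait = "V", pve = 0.18, pve_class = "level", lg = "LG04", cm = 12),
    list(trait = "BD", pve = 0.15, pve_class = "level", lg = "LG04",
         cm = 12.5))
  cfg$qtl$n_perm <- 200
  cfg$hotspots$n_perm <- 200
  cfg$panel$snps_per_region <- 500L
  cfg$panel$max_region_bp <- 15000L
  cfg$ld$n_perm <- 200
  cfg$ld$max_pairs <- 10L
  cfg$epistasis$max_candidates <- 15L
  cfg
}
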