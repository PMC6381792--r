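# Windowed diversity and differentiation statistics over fixed genomic
# windows (250 bp by default), and the joint empirical-outlier selection scan
# between subpopulation pairs.
#
# Haplotype counts are taken from diploid genotypes assuming HWE-independent
# alleles (n = 2 x non-missing individuals); statistics use complete cases
# per site and are never imputed.

#' Tile intervals into fixed-size non-overlapping windows
#'
#' @param intervals data.frame (`chrom`, `start`, `end`), 0-based half-open.
#' @param size window size in bp (default 250).
#' @param flank extension added on both sides of each interval before tiling
#'   (default 0; the selection scan uses 10 kb).
#' @return data.frame of windows (`chrom`, `start`, `end`).
#' @export
tile_windows <- function(intervals, size = 250L, flank = 0L) {
  iv <- genomic_intervals(intervals)
  out <- lapply(seq_len(nrow(iv)), function(i) {
    lo <- max(0L, iv$start[i] - flank)
    hi <- iv$end[i] + flank
    starts <- seq(lo, hi - 1L, by = size)
    data.frame(chrom = iv$chrom[i], start = starts,
               end = pmin(starts + size, hi), stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, out))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# per-site pi, allele count, haplotype count within a set of individuals
site_summaries <- function(dosage) {
  k <- colSums(!is.na(dosage))
  n <- 2 * k
  c_alt <- colSums(dosage, na.rm = TRUE)
  pi <- ifelse(n >= 2, 2 * c_alt * (n - c_alt) / (n * pmax(n - 1, 1)), NA_real_)
  list(n = n, c = c_alt, pi = pi,
       seg = n >= 2 & c_alt > 0 & c_alt < n)
}

a1_const <- function(n) vapply(n, function(nn)
  if (nn >= 2) sum(1 / seq_len(nn - 1)) else NA_real_, numeric(1))

# indices of sites falling in each window, via binary search on sorted site
# positions per chromosome; returns a list parallel to the window rows
sites_per_window <- function(sites, windows) {
  out <- rep(list(integer(0)), nrow(windows))
  pos0 <- sites$pos - 1L
  for (ch in unique(windows$chrom)) {
    wix <- which(windows$chrom == ch)
    six <- which(sites$chrom == ch)
    if (!length(six)) next
    o <- order(pos0[six])
    six <- six[o]
    ps <- pos0[six]
    i1 <- findInterval(windows$start[wix] - 0.5, ps) + 1L
    i2 <- findInterval(windows$end[wix] - 0.5, ps)
    for (k in seq_along(wix))
      if (i1[k] <= i2[k]) out[[wix[k]]] <- six[i1[k]:i2[k]]
  }
  out
}

#' Per-window nucleotide diversity and Watterson's theta
#'
#' For each window: per-site pi = 2c(n-c)/(n(n-1)) with c the alternate-allele
#' count and n the haplotype count (2 x non-missing individuals); window pi is
#' the per-site sum divided by window length in bp (monomorphic positions
#' included); theta_w divides each segregating site by its own a1 = sum 1/i.
#'
#' @param g a `genotype_matrix`.
#' @param windows window data.frame from [tile_windows()].
#' @param subpop subpopulation label to restrict to (default: all
#'   individuals).
#' @return data.frame per window: `chrom`, `start`, `end`, `S`, `pi`,
#'   `theta_w`, `pi_total` (sum of per-site pi, Tajima's numerator scale),
#'   `n_hap` (mean haplotype count at segregating sites), `tajima_d`
#'   (NA when S = 0), `defined`.
#' @export
window_diversity <- function(g, windows, subpop = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (!is.null(subpop)) {
    if (is.null(g$subpop)) stop("genotype matrix has no subpop labels")
    d <- d[g$subpop == subpop, , drop = FALSE]
  }
  ss <- site_summaries(d)
  out <- windows
  len <- windows$end - windows$start
  out$S <- 0L
  out$pi <- 0
  out$theta_w <- 0
  out$pi_total <- 0
  out$n_hap <- NA_real_
  out$tajima_d <- NA_real_
  out$defined <- TRUE                          # empty window = monomorphic
  spw <- sites_per_window(g$sites, windows)
  nper <- lengths(spw)
  widx <- rep.int(seq_along(spw), nper)        # site -> window
  sidx <- unlist(spw, use.names = FALSE)
  usable <- ss$n[sidx] >= 2
  widx <- widx[usable]; sidx <- sidx[usable]
  if (length(sidx)) {
    agg <- function(v) {
      r <- rowsum(v, widx)
      stats::setNames(r[, 1], rownames(r))
    }
    put <- function(col, v) { out[[col]][as.integer(names(v))] <- v; out }
    out <- put("pi_total", agg(ss$pi[sidx]))
    seg <- ss$seg[sidx]
    inv_a1 <- ifelse(seg, 1 / a1_const(ifelse(seg, ss$n[sidx], 2)), 0)
    out <- put("theta_w", agg(inv_a1))
    out <- put("S", agg(as.numeric(seg)))
    nsum <- agg(ifelse(seg, ss$n[sidx], 0))
    wS <- out$S[as.integer(names(nsum))]
    nh <- round(ifelse(wS > 0, nsum / wS, NA_real_))
    out$n_hap[as.integer(names(nsum))] <- nh
  }
  # windows that contain sites but none with >= 1 called individual pair
  n_use <- tabulate(widx, nbins = nrow(windows))
  bad <- nper > 0 & n_use == 0
  out$defined[bad] <- FALSE
  out$S[bad] <- NA_integer_
  out$pi_total[bad] <- NA_real_
  out$theta_w[bad] <- NA_real_
  out$pi <- out$pi_total / len
  out$theta_w <- out$theta_w / len
  td <- which(!is.na(out$S) & out$S > 0 & !is.na(out$n_hap) & out$n_hap >= 4)
  for (i in td)
    out$tajima_d[i] <- tajimas_d(out$S[i], out$n_hap[i], out$pi_total[i])
  out
}

#' Tajima's D
#'
#' Normalised difference between the pairwise-difference estimator (pi) and
#' Watterson's S-based estimator of the scaled mutation rate, using the
#' Tajima (1989) constants. Undefined (NA, distinct from 0) when `S = 0`.
#'
#' @param S number of segregating sites.
#' @param n haplotype sample size (>= 4 for a stable denominator).
#' @param pi_total sum of per-site pairwise diversity over the same sites
#'   (i.e. the mean number of pairwise differences).
#' @return Tajima's D.
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (S == 0) return(NA_real_)
  stopifnot(n >= 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) per-site variance components for two
# subpopulations, from genotype counts (r = 2, two alleles).
wc_components <- function(dA, dB) {
  comp_pop <- function(d) {
    k <- colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / (2 * k)
    het <- colSums(d == 1, na.rm = TRUE) / k
    list(n = k, p = p, h = het)
  }
  A <- comp_pop(dA); B <- comp_pop(dB)
  r <- 2
  ok <- A$n >= 2 & B$n >= 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Per-window Weir-Cockerham Fst between two subpopulations
#'
#' Per-site variance components a (among-population), b, c are combined per
#' window as a ratio of sums: Fst = sum(a) / sum(a + b + c). Negative values
#' are reported raw with a flag; windows monomorphic overall are undefined.
#'
#' @param g a `genotype_matrix` with subpop labels.
#' @param windows window data.frame.
#' @param subpopA,subpopB the two subpopulation labels.
#' @return data.frame per window: `chrom`, `start`, `end`, `fst`,
#'   `n_sites`, `negative` flag.
#' @export
weir_cockerham_fst <- function(g, windows, subpopA, subpopB) {
  stopifnot(inherits(g, "genotype_matrix"), !is.null(g$subpop))
  dA <- g$dosage[g$subpop == subpopA, , drop = FALSE]
  dB <- g$dosage[g$subpop == subpopB, , drop = FALSE]
  wc <- wc_components(dA, dB)
  out <- windows
  out$fst <- NA_real_
  out$n_sites <- 0L
  out$negative <- FALSE
  spw <- sites_per_window(g$sites, windows)
  widx <- rep.int(seq_along(spw), lengths(spw))
  sidx <- unlist(spw, use.names = FALSE)
  keep <- !is.na(wc$a[sidx])
  widx <- widx[keep]; sidx <- sidx[keep]
  if (length(sidx)) {
    num <- rowsum(wc$a[sidx], widx)
    den <- rowsum(wc$a[sidx] + wc$b[sidx] + wc$c[sidx], widx)
    w <- as.integer(rownames(num))
    out$n_sites[w] <- tabulate(widx, nbins = nrow(windows))[w]
    fst <- ifelse(abs(den[, 1]) < 1e-12, NA_real_, num[, 1] / den[, 1])
    out$fst[w] <- fst
    out$negative[w] <- !is.na(fst) & fst < 0
  }
  out
}

#' Reduction-of-diversity statistic
#'
#' `ROD = 1 - pi_objective / pi_reference`; near 1 indicates a
#' diversity-eliminating sweep in the objective population. Undefined when
#' the reference diversity is 0.
#'
#' @param pi_obj,pi_ref per-window diversity in objective and reference
#'   subpopulations.
#' @return numeric vector of ROD values.
#' @export
rod_statistic <- function(pi_obj, pi_ref) {
  ifelse(is.na(pi_ref) | pi_ref <= 0, NA_real_, 1 - pi_obj / pi_ref)
}

#' Combined per-window statistics for a subpopulation pair
#'
#' Convenience wrapper producing, per window: diversity statistics for the
#' objective and reference subpopulations, pairwise Weir-Cockerham Fst,
#' `log_ratio = log(pi_ref / pi_obj)` (large = diversity reduced in the
#' objective population), and ROD.
#'
#' @param g a `genotype_matrix` with subpop labels.
#' @param windows window data.frame (e.g. [tile_windows()] over SHRs with a
#'   10-kb flank).
#' @param objective,reference subpopulation labels.
#' @return data.frame, one row per window.
#' @export
window_stats <- function(g, windows, objective, reference) {
  obj <- window_diversity(g, windows, objective)
  ref <- window_diversity(g, windows, reference)
  fst <- weir_cockerham_fst(g, windows, objective, reference)
  out <- windows
  out$S_obj <- obj$S; out$pi_obj <- obj$pi; out$theta_obj <- obj$theta_w
  out$d_obj <- obj$tajima_d
  out$S_ref <- ref$S; out$pi_ref <- ref$pi; out$theta_ref <- ref$theta_w
  out$d_ref <- ref$tajima_d
  out$fst <- fst$fst
  out$fst_negative <- fst$negative
  # log(pi_ref/pi_obj): +Inf marks complete loss of diversity in the
  # objective subpopulation while the reference still segregates (maximal
  # reduction, always flag-eligible); NA when the reference itself carries
  # no diversity in the window
  out$log_ratio <- ifelse(
    !is.na(out$pi_ref) & out$pi_ref > 0,
    ifelse(out$pi_obj > 0, log(out$pi_ref / out$pi_obj), Inf),
    NA_real_)
  out$rod <- rod_statistic(out$pi_obj, out$pi_ref)
  out$objective <- objective
  out$reference <- reference
  out
}

#' Joint empirical-outlier windows (top-q Fst AND top-q diversity reduction)
#'
#' A window is flagged only when it lies in the top `q` of the empirical Fst
#' distribution AND in the top `q` of `log(pi_ref/pi_obj)` for the same
#' subpopulation pair.
#'
#' @param stats per-window statistics from [window_stats()].
#' @param q upper tail fraction (default 0.01).
#' @return `stats` with a logical `outlier` column; quantile cut-offs in
#'   attributes `fst_cut` and `ratio_cut`.
#' @export
joint_outlier_windows <- function(stats, q = 0.01) {
  stopifnot(q > 0, q <= 1)
  ok <- !is.na(stats$fst) & !is.na(stats$log_ratio)
  if (sum(ok) < 100)
    warning("fewer than 100 windows with defined statistics; ",
            "empirical quantiles will be unstable")
  fst_cut <- stats::quantile(stats$fst[ok], 1 - q, names = FALSE)
  ratio_cut <- stats::quantile(stats$log_ratio[ok], 1 - q, names = FALSE)
  stats$outlier <- ok & stats$fst >= fst_cut & stats$log_ratio >= ratio_cut
  attr(stats, "fst_cut") <- fst_cut
  attr(stats, "ratio_cut") <- ratio_cut
  stats
}

#' Merge flagged windows into candidate selective regions
#'
#' Contiguous (or near-contiguous, gap <= `max_gap` windows) flagged windows
#' are merged; a single flagged window yields a region of one window size.
#'
#' @param stats output of [joint_outlier_windows()] (needs `outlier`).
#' @param max_gap maximum number of unflagged windows bridged (default 1).
#' @param window_size window size in bp (default 250).
#' @return data.frame of regions: `region`, `chrom`, `start`, `end`,
#'   `n_windows`, `mean_fst`, `mean_log_ratio`, `objective`, `reference`.
#' @export
merge_regions <- function(stats, max_gap = 1L, window_size = 250L) {
  fl <- stats[which(stats$outlier), , drop = FALSE]
  empty <- data.frame(region = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_windows = integer(0), mean_fst = numeric(0),
                      mean_log_ratio = numeric(0),
                      objective = character(0), reference = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fl) == 0) return(empty)
  fl <- fl[order(fl$chrom, fl$start), ]
  gap_bp <- max_gap * window_size
  newgrp <- c(TRUE, fl$chrom[-1] != fl$chrom[-nrow(fl)] |
                fl$start[-1] - fl$end[-nrow(fl)] > gap_bp)
  grp <- cumsum(newgrp)
  out <- do.call(rbind, lapply(split(seq_len(nrow(fl)), grp), function(ix) {
    data.frame(chrom = fl$chrom[ix[1]], start = min(fl$start[ix]),
               end = max(fl$end[ix]), n_windows = length(ix),
               mean_fst = mean(fl$fst[ix], na.rm = TRUE),
               mean_log_ratio = mean(fl$log_ratio[ix], na.rm = TRUE),
               objective = fl$objective[ix[1]],
               reference = fl$reference[ix[1]], stringsAsFactors = FALSE)
  }))
  out <- cbind(region = sprintf("SEL%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Confirm candidate selective regions with Tajima's D
#'
#' Per region, a one-sided rank-sum (Wilcoxon) test compares window-level
#' Tajima's D between the objective and reference subpopulations; the region
#' is confirmed when P < `alpha` and the objective mean D is lower. Regions
#' with fewer than 3 windows with defined D in either subpopulation are "not
#' evaluable".
#'
#' @param regions output of [merge_regions()].
#' @param stats per-window statistics from [window_stats()].
#' @param alpha significance level (default 0.05).
#' @return `regions` with columns `tajima_p`, `confirmed`, `evaluable`.
#' @export
confirm_with_tajima <- function(regions, stats, alpha = 0.05) {
  if (nrow(regions) == 0) {
    regions$tajima_p <- numeric(0)
    regions$confirmed <- logical(0)
    regions$evaluable <- logical(0)
    return(regions)
  }
  regions$tajima_p <- NA_real_
  regions$confirmed <- FALSE
  regions$evaluable <- FALSE
  for (i in seq_len(nrow(regions))) {
    wix <- which(stats$chrom == regions$chrom[i] &
                   stats$start >= regions$start[i] &
                   stats$end <= regions$end[i])
    d_obj <- stats$d_obj[wix]
    d_ref <- stats$d_ref[wix]
    if (sum(!is.na(d_obj)) < 3 || sum(!is.na(d_ref)) < 3) next
    regions$evaluable[i] <- TRUE
    wt <- suppressWarnings(
      stats::wilcox.test(d_obj, d_ref, alternative = "less"))
    regions$tajima_p[i] <- wt$p.value
    regions$confirmed[i] <- !is.na(wt$p.value) && wt$p.value < alpha &&
      mean(d_obj, na.rm = TRUE) < mean(d_ref, na.rm = TRUE)
  }
  regions
}

#' Classify SNP fixation status across subpopulations
#'
#' `nearly_fixed`: MAF < `maf_cut` in at least one subpopulation but non-zero
#' in all; `completely_fixed`: MAF = 0 in at least one subpopulation;
#' otherwise `segregating`. Subpopulations with all calls missing at a SNP
#' are excluded (and flagged).
#'
#' @param g a `genotype_matrix` with subpop labels.
#' @param maf_cut near-fixation MAF threshold (default 0.05).
#' @return data.frame per SNP: `id`, per-subpop MAF columns, `class`,
#'   `n_subpops_used`.
#' @export
classify_fixation <- function(g, maf_cut = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"), !is.null(g$subpop))
  pops <- unname(unique(g$subpop))
  mafs <- sapply(pops, function(s)
    site_maf(g, individuals = which(g$subpop == s)))
  if (is.null(dim(mafs))) mafs <- matrix(mafs, nrow = 1,
                                         dimnames = list(NULL, pops))
  cls <- apply(mafs, 1, function(m) {
    m <- m[!is.na(m)]
    if (!length(m)) return(NA_character_)
    if (any(m == 0)) "completely_fixed"
    else if (any(m < maf_cut)) "nearly_fixed"
    else "segregating"
  })
  out <- data.frame(id = g$sites$id, stringsAsFactors = FALSE)
  for (s in pops) out[[paste0("maf_", s)]] <- mafs[, s]
  out$class <- cls
  out$n_subpops_used <- rowSums(!is.na(mafs))
  out
}
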