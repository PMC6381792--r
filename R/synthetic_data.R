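# Simulators for the two study designs: a pseudo-testcross full-sib family
# genotyped on a multi-LG linkage map, and a three-subpopulation association
# panel with Balding-Nichols differentiation. Both return ground-truth records
# (planted QTL/QTN, sweeps, epistatic pairs) so downstream stages can be
# scored against truth.

#' Haldane map function
#'
#' Recombination fraction for a map distance in cM, assuming no interference:
#' `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d_cm map distance in centiMorgans.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Inverse Haldane map function
#' @param r recombination fraction in `[0, 0.5)`.
#' @return map distance in cM.
#' @export
haldane_cm <- function(r) -50 * log(1 - 2 * r)

# ---- configs ---------------------------------------------------------------

#' Full-sib family simulation configuration
#'
#' Defaults are desk-scale (300 progeny) so the whole pipeline runs in
#' seconds; `full_scale = TRUE` switches to the dimensions of the emulated
#' study design (1,200 progeny, ~67 markers per LG).
#'
#' @param n_progeny number of full-sib progeny.
#' @param n_lg number of linkage groups (default 19).
#' @param markers_per_lg markers per linkage group.
#' @param mean_interval_cm mean adjacent-marker spacing in cM (default 2.3).
#' @param n_timepoints longitudinal measurement occasions (default 12).
#' @param traits trait labels.
#' @param ar1_rho AR(1) correlation of the residual across timepoints.
#' @param missing_rate marker-call missing rate.
#' @param full_scale if TRUE, use full study dimensions.
#' @param seed RNG seed used by [simulate_fullsib()].
#' @return object of class `family_config`.
#' @export
family_config <- function(n_progeny = if (full_scale) 1200L else 300L,
                          n_lg = 19L,
                          markers_per_lg = if (full_scale) 67L else 15L,
                          mean_interval_cm = 2.3,
                          n_timepoints = 12L,
                          traits = c("H", "BD", "V"),
                          ar1_rho = 0.6,
                          missing_rate = 0.02,
                          full_scale = FALSE,
                          seed = 1L) {
  stopifnot(n_progeny >= 2, n_lg >= 1, markers_per_lg >= 2,
            mean_interval_cm > 0, ar1_rho >= 0, ar1_rho < 1)
  structure(list(n_progeny = as.integer(n_progeny), n_lg = as.integer(n_lg),
                 markers_per_lg = as.integer(markers_per_lg),
                 mean_interval_cm = mean_interval_cm,
                 n_timepoints = as.integer(n_timepoints), traits = traits,
                 ar1_rho = ar1_rho, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "family_config")
}

#' Association panel simulation configuration
#'
#' Emulates a panel of unrelated individuals from three climatic regions
#' (labels S, NW, NE). Desk-scale default is 150 individuals (60/40/50);
#' `full_scale = TRUE` uses the study sizes 180/95/160 (total 435).
#' Subpopulation allele frequencies follow the Balding-Nichols model: for
#' ancestral frequency p and differentiation F, the subpopulation frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F).
#'
#' @param sizes named integer vector of subpopulation sizes.
#' @param f Balding-Nichols F, recycled across subpopulations (default 0.10).
#' @param n_regions number of SHR-like genomic regions carrying SNPs.
#' @param region_length region length in bp.
#' @param snps_per_region SNP count per region.
#' @param missing_rate genotype missing-call rate.
#' @param maf_dist ancestral allele-frequency distribution: `"neutral"`
#'   (default; density proportional to `p^-sfs_exponent`, so that after
#'   Balding-Nichols drift the within-subpopulation site-frequency spectrum
#'   is approximately the neutral 1/p spectrum and windowed Tajima's D is
#'   centred near 0) or `"uniform"`.
#' @param sfs_exponent exponent of the neutral ancestral draw (default 1.4,
#'   calibrated for the default F = 0.10).
#' @param maf_range truncation range of the ancestral frequency; default
#'   `c(0.001, 0.999)` for `"neutral"`, `c(0.05, 0.5)` for `"uniform"`.
#' @param n_founder_haps if non-NULL, genotypes are built by mosaic copying
#'   from this many founder haplotypes per region and subpopulation, which
#'   induces LD that decays with distance; NULL (default) simulates sites
#'   independently.
#' @param copy_switch_rate per-bp founder switch rate for mosaic copying.
#' @param h2_poly variance fraction of the polygenic term in simulated
#'   phenotypes.
#' @param timepoints phenotype timepoint labels (default 9 occasions).
#' @param traits trait labels.
#' @param full_scale if TRUE, use study dimensions.
#' @param seed RNG seed used by [simulate_panel()].
#' @return object of class `panel_config`.
#' @export
panel_config <- function(sizes = if (full_scale)
                           c(S = 180L, NW = 95L, NE = 160L) else
                           c(S = 60L, NW = 40L, NE = 50L),
                         f = 0.10,
                         n_regions = 5L,
                         region_length = 25000L,
                         snps_per_region = 400L,
                         missing_rate = 0.02,
                         maf_dist = c("neutral", "uniform"),
                         sfs_exponent = 1.4,
                         maf_range = NULL,
                         n_founder_haps = NULL,
                         copy_switch_rate = 1e-4,
                         h2_poly = 0.3,
                         timepoints = c(paste0("T1_0", 1:5),
                                        "T2", "T3", "T4", "T5"),
                         traits = c("H", "BD", "V"),
                         full_scale = FALSE,
                         seed = 1L) {
  stopifnot(all(sizes >= 2), all(f > 0), all(f < 1))
  maf_dist <- match.arg(maf_dist)
  if (is.null(maf_range))
    maf_range <- if (maf_dist == "neutral") c(0.001, 0.999) else c(0.05, 0.5)
  f <- rep_len(f, length(sizes))
  names(f) <- names(sizes)
  structure(list(sizes = sizes, f = f, n_regions = as.integer(n_regions),
                 region_length = as.integer(region_length),
                 snps_per_region = as.integer(snps_per_region),
                 missing_rate = missing_rate, maf_dist = maf_dist,
                 sfs_exponent = sfs_exponent, maf_range = maf_range,
                 n_founder_haps = n_founder_haps,
                 copy_switch_rate = copy_switch_rate,
                 h2_poly = h2_poly, timepoints = timepoints, traits = traits,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Specification of a planted quantitative trait nucleotide (QTN)
#'
#' For the full-sib simulator give a map position (`lg`, `cm`); for the panel
#' simulator give a site index (`site`, column of the simulated genotype
#' matrix) or leave `site = NA` to have one drawn at random. Per-timepoint
#' target PVE follows one of four trajectory classes.
#'
#' @param trait trait affected.
#' @param pve target proportion of phenotypic variance explained at the
#'   trajectory maximum, in `[0, 1)`.
#' @param pve_class trajectory of PVE over timepoints: `"level"`,
#'   `"increasing"`, `"decreasing"` or `"increase-then-level"`.
#' @param lg,cm map position for the full-sib simulator.
#' @param site genotype-matrix column index for the panel simulator.
#' @param dom_ratio panel only: dominance-to-additive variance ratio
#'   (0 = purely additive; `Inf` = purely dominant).
#' @param min_maf panel only: minimum realized MAF required when the site is
#'   drawn at random (default 0.1; use ~0.3 when all three genotype classes
#'   must be well populated).
#' @return object of class `qtn_spec`.
#' @export
qtn_spec <- function(trait, pve, pve_class = "level",
                     lg = NA, cm = NA, site = NA, dom_ratio = 0,
                     min_maf = 0.1) {
  stopifnot(pve >= 0, pve < 1,
            pve_class %in% c("level", "increasing", "decreasing",
                             "increase-then-level"))
  structure(list(trait = trait, pve = pve, pve_class = pve_class,
                 lg = lg, cm = cm, site = site, dom_ratio = dom_ratio,
                 min_maf = min_maf),
            class = "qtn_spec")
}

#' Specification of a planted selective sweep
#'
#' Within the objective subpopulation, allele frequencies of sites in the
#' target interval are pushed toward fixation: the minor-allele side of the
#' frequency is multiplied by `rho_sweep`, so `rho_sweep = 0.05` leaves ~5%
#' of the pre-sweep diversity.
#'
#' @param chrom,start,end target interval (0-based half-open).
#' @param subpop objective subpopulation label.
#' @param rho_sweep diversity retention factor in `(0, 1]`.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, start, end, subpop, rho_sweep = 0.05) {
  stopifnot(rho_sweep > 0, rho_sweep <= 1, start < end)
  structure(list(chrom = chrom, start = start, end = end, subpop = subpop,
                 rho_sweep = rho_sweep), class = "sweep_spec")
}

#' Specification of a planted epistatic pair
#'
#' @param siteA,siteB genotype-matrix column indices.
#' @param trait trait affected.
#' @param pve target variance fraction of the interaction term.
#' @param type interaction component planted: `"axa"`, `"axd"`, `"dxa"` or
#'   `"dxd"` (pure dominance-by-dominance gives the checkerboard pattern of
#'   3x3 class means with no marginal effects).
#' @param pve_class PVE trajectory over timepoints (see [qtn_spec()]).
#' @param min_maf minimum realized MAF when sites are drawn at random
#'   (default 0.2; the corner genotype classes need occupants).
#' @return object of class `epi_spec`.
#' @export
epi_spec <- function(siteA, siteB, trait, pve, type = "dxd",
                     pve_class = "level", min_maf = 0.2) {
  stopifnot(type %in% c("axa", "axd", "dxa", "dxd"), pve >= 0, pve < 1)
  structure(list(siteA = siteA, siteB = siteB, trait = trait, pve = pve,
                 type = type, pve_class = pve_class, min_maf = min_maf),
            class = "epi_spec")
}

pve_trajectory <- function(pve, pve_class, n_t) {
  switch(pve_class,
    level = rep(pve, n_t),
    increasing = seq(pve / n_t, pve, length.out = n_t),
    decreasing = seq(pve, pve / n_t, length.out = n_t),
    `increase-then-level` = {
      half <- ceiling(n_t / 2)
      c(seq(pve / half, pve, length.out = half), rep(pve, n_t - half))
    })
}

# ---- full-sib simulator ----------------------------------------------------

#' Simulate a pseudo-testcross full-sib linkage population
#'
#' Markers segregate 1:1 from the informative parent (two-class coding 0/1).
#' Progeny genotypes arise from Markovian recombination along each linkage
#' group under the Haldane map function (no interference). Phenotypes are the
#' sum of planted QTN effects plus an AR(1)-correlated residual across
#' timepoints (marginal variance 1).
#'
#' @param config a [family_config()].
#' @param qtns list of [qtn_spec()] with `lg`/`cm` set. Summed target PVE per
#'   trait must stay below 1.
#' @return a [linkage_dataset()] with attribute `truth`: the map, QTN table
#'   (per-timepoint effect `a` and target PVE), latent QTN genotypes, and the
#'   seed used.
#' @export
simulate_fullsib <- function(config = family_config(), qtns = list()) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  n <- config$n_progeny
  n_t <- config$n_timepoints
  tp <- sprintf("T%02d", seq_len(n_t))

  # map: exponential-ish spacings with the configured mean, floored at 0.2 cM
  map <- do.call(rbind, lapply(seq_len(config$n_lg), function(l) {
    gaps <- pmax(0.2, stats::rexp(config$markers_per_lg - 1,
                                  rate = 1 / config$mean_interval_cm))
    data.frame(lg = sprintf("LG%02d", l),
               marker = sprintf("M%02d_%03d", l, seq_len(config$markers_per_lg)),
               cm = round(cumsum(c(0, gaps)), 3),
               stringsAsFactors = FALSE)
  }))

  # attach QTNs as latent loci on the map
  qtn_tab <- NULL
  if (length(qtns)) {
    qtn_tab <- do.call(rbind, lapply(seq_along(qtns), function(i) {
      q <- qtns[[i]]
      if (is.na(q$lg) || is.na(q$cm))
        stop("full-sib QTNs need lg and cm")
      data.frame(qtn = paste0("Q", i), lg = q$lg, cm = q$cm, trait = q$trait,
                 pve = q$pve, pve_class = q$pve_class,
                 stringsAsFactors = FALSE)
    }))
    if (!all(qtn_tab$lg %in% map$lg))
      stop("QTN lg not on the simulated map")
  }

  # recombination along each LG; latent QTN loci share the chain
  calls <- matrix(NA_integer_, n, nrow(map),
                  dimnames = list(sprintf("P%04d", seq_len(n)), map$marker))
  qtn_geno <- if (!is.null(qtn_tab))
    matrix(NA_integer_, n, nrow(qtn_tab),
           dimnames = list(rownames(calls), qtn_tab$qtn)) else NULL
  for (l in unique(map$lg)) {
    mk <- map[map$lg == l, ]
    pos <- mk$cm
    is_marker <- rep(TRUE, length(pos))
    labs <- mk$marker
    if (!is.null(qtn_tab) && any(qtn_tab$lg == l)) {
      qq <- qtn_tab[qtn_tab$lg == l, ]
      pos <- c(pos, qq$cm)
      is_marker <- c(is_marker, rep(FALSE, nrow(qq)))
      labs <- c(labs, qq$qtn)
    }
    o <- order(pos)
    pos <- pos[o]; is_marker <- is_marker[o]; labs <- labs[o]
    r <- haldane_r(diff(pos))
    z <- matrix(0L, n, length(pos))
    z[, 1] <- stats::rbinom(n, 1, 0.5)
    for (k in seq_along(r)) {
      flip <- stats::rbinom(n, 1, r[k])
      z[, k + 1] <- ifelse(flip == 1, 1L - z[, k], z[, k])
    }
    calls[, labs[is_marker]] <- z[, is_marker, drop = FALSE]
    if (any(!is_marker))
      qtn_geno[, labs[!is_marker]] <- z[, !is_marker, drop = FALSE]
  }

  # phenotypes: QTN effects (score +/-1, var 1) + AR(1) residual, var 1
  rho <- config$ar1_rho
  a_tab <- NULL
  pheno <- vector("list", length(config$traits))
  names(pheno) <- config$traits
  for (tr in config$traits) {
    idx <- if (!is.null(qtn_tab)) which(qtn_tab$trait == tr) else integer(0)
    pve_mat <- if (length(idx))
      sapply(idx, function(i) pve_trajectory(qtn_tab$pve[i],
                                             qtn_tab$pve_class[i], n_t))
    else matrix(0, n_t, 0)                     # n_t x n_qtn
    tot <- rowSums(pve_mat)
    if (any(tot >= 1))
      stop("summed target PVE per phenotype set must be < 1 (trait ", tr, ")")
    a_mat <- sqrt(pve_mat / (1 - tot))         # effect so that PVE = target
    e <- matrix(stats::rnorm(n * n_t), n, n_t)
    if (n_t > 1) for (j in 2:n_t)
      e[, j] <- rho * e[, j - 1] + sqrt(1 - rho^2) * e[, j]
    y <- e
    if (length(idx)) {
      s <- 2 * qtn_geno[, idx, drop = FALSE] - 1
      y <- y + s %*% t(a_mat)
    }
    pheno[[tr]] <- data.frame(individual = rep(rownames(calls), n_t),
                              trait = tr,
                              timepoint = rep(tp, each = n),
                              value = as.vector(y),
                              stringsAsFactors = FALSE)
    if (length(idx))
      a_tab <- rbind(a_tab,
                     data.frame(qtn = qtn_tab$qtn[idx][col(a_mat)],
                                trait = tr,
                                timepoint = tp[row(a_mat)],
                                a = as.vector(a_mat),
                                pve = as.vector(pve_mat),
                                stringsAsFactors = FALSE))
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(calls)) < config$missing_rate
    calls[mask] <- NA_integer_
  }
  out <- linkage_dataset(map, calls, do.call(rbind, pheno))
  attr(out, "truth") <- list(qtn = qtn_tab, effects = a_tab,
                             qtn_geno = qtn_geno, seed = config$seed)
  out
}

#' Simulate an anchor-marker table for a linkage map
#'
#' Assigns genomic coordinates to a subset of markers on each LG, emulating
#' gene-derived anchors: chromosome `Chrkk` for `LGkk`, bp increasing with cM
#' at a locally varying scale (log-normal jitter around `bp_per_cm`).
#'
#' @param map linkage map data.frame (`lg`, `marker`, `cm`).
#' @param bp_per_cm mean physical-per-genetic scale (default 250 kb/cM).
#' @param frac fraction of markers that are anchors (default 0.3).
#' @param jitter_sd log-normal sd of the local scale.
#' @param seed RNG seed.
#' @return data.frame with columns `marker`, `lg`, `cm`, `chrom`, `bp`.
#' @export
simulate_anchors <- function(map, bp_per_cm = 2.5e5, frac = 0.3,
                             jitter_sd = 0.2, seed = 1L) {
  set.seed(seed)
  out <- lapply(split(map, map$lg), function(mk) {
    mk <- mk[order(mk$cm), ]
    scale <- bp_per_cm * exp(stats::rnorm(nrow(mk) - 1, 0, jitter_sd))
    bp <- cumsum(c(1e5, diff(mk$cm) * scale))
    k <- max(3L, round(frac * nrow(mk)))
    pick <- sort(unique(round(seq(1, nrow(mk), length.out = k))))
    lgnum <- sub("^LG", "", unique(mk$lg))
    data.frame(marker = mk$marker[pick], lg = unique(mk$lg),
               cm = mk$cm[pick], chrom = paste0("Chr", lgnum),
               bp = round(bp[pick]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---- panel simulator -------------------------------------------------------

#' Simulate a structured association panel
#'
#' Balding-Nichols subpopulation frequencies around a Uniform ancestral MAF,
#' Hardy-Weinberg genotypes within subpopulations (optionally with founder-
#' haplotype mosaic copying to induce distance-decaying LD), planted sweeps,
#' and phenotypes for every trait x timepoint set built from planted
#' additive/dominance QTNs, epistatic pairs, a kinship-structured polygenic
#' term, and Gaussian noise.
#'
#' @param config a [panel_config()].
#' @param qtns list of [qtn_spec()] with `site` set (or NA for random).
#' @param sweeps list of [sweep_spec()].
#' @param epi_pairs list of [epi_spec()].
#' @param regions optional data.frame (`chrom`, `start`, `end`) of regions to
#'   carry SNPs; default generates `config$n_regions` regions.
#' @return list with elements `genotypes` (a `genotype_matrix` with subpop
#'   labels), `phenotypes` (long data.frame), and `truth` (planted loci with
#'   implied per-set additive/dominance effects, sweep intervals, regions,
#'   seed).
#' @export
simulate_panel <- function(config = panel_config(), qtns = list(),
                           sweeps = list(), epi_pairs = list(),
                           regions = NULL) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  sizes <- config$sizes
  n <- sum(sizes)
  pops <- rep(names(sizes), sizes)
  ids <- sprintf("I%04d", seq_len(n))

  if (is.null(regions)) {
    regions <- data.frame(
      chrom = sprintf("Chr%02d", seq_len(config$n_regions)),
      start = as.integer(stats::runif(config$n_regions, 0, 5e6)),
      stringsAsFactors = FALSE)
    regions$end <- regions$start + config$region_length
    regions$name <- sprintf("SHR%02d", seq_len(config$n_regions))
  } else {
    regions <- genomic_intervals(regions)
  }

  sites <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    m <- config$snps_per_region
    pos0 <- sort(sample.int(regions$end[i] - regions$start[i] - 1, m)) +
      regions$start[i]
    data.frame(chrom = regions$chrom[i], pos = pos0 + 1L,   # 1-based VCF-style
               ref = sample(c("A", "C", "G", "T"), m, TRUE),
               region = regions$name[i], stringsAsFactors = FALSE)
  }))
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  m <- nrow(sites)

  p_anc <- if (config$maf_dist == "uniform")
    stats::runif(m, config$maf_range[1], config$maf_range[2])
  else {
    # density ~ p^-a on [lo, hi], inverse-CDF draw
    a <- config$sfs_exponent
    lo <- config$maf_range[1]; hi <- config$maf_range[2]
    u <- stats::runif(m)
    if (abs(a - 1) < 1e-9) lo * (hi / lo)^u
    else (lo^(1 - a) + u * (hi^(1 - a) - lo^(1 - a)))^(1 / (1 - a))
  }
  freq <- sapply(names(sizes), function(s) {
    f <- config$f[[s]]
    stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  })                                                     # m x n_subpop
  freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)

  # frequency-level hitchhiking (independent-site mode): the allele carried
  # by the sweeping haplotype fixes, i.e. with probability p the alternate
  # allele rises to ~1, otherwise it collapses to ~0; rho_sweep is the
  # residual diversity retained. In founder-copying mode sweeps act at the
  # haplotype level instead (below).
  if (is.null(config$n_founder_haps)) {
    for (sw in sweeps) {
      stopifnot(inherits(sw, "sweep_spec"))
      hit <- sites$chrom == sw$chrom & sites$pos - 1L >= sw$start &
        sites$pos - 1L < sw$end
      pcol <- freq[hit, sw$subpop]
      up <- stats::runif(length(pcol)) < pcol
      freq[hit, sw$subpop] <- ifelse(up, 1 - sw$rho_sweep * (1 - pcol),
                                     sw$rho_sweep * pcol)
    }
  }

  dosage <- matrix(NA_integer_, n, m)
  for (s in names(sizes)) {
    rows <- which(pops == s)
    if (is.null(config$n_founder_haps)) {
      dosage[rows, ] <- t(matrix(stats::rbinom(length(rows) * m, 2,
                                               rep(freq[, s], length(rows))),
                                 m, length(rows)))
    } else {
      H <- config$n_founder_haps
      for (rg in unique(sites$region)) {
        cols <- which(sites$region == rg)
        founders <- matrix(stats::rbinom(H * length(cols), 1,
                                         rep(freq[cols, s], each = H)),
                           H, length(cols))
        # haplotype-level sweep: within the interval every founder of the
        # objective subpopulation carries the swept haplotype's allele; a
        # fraction rho_sweep of sites escape and keep their own alleles
        for (sw in sweeps) {
          stopifnot(inherits(sw, "sweep_spec"))
          if (s != sw$subpop) next
          swcols <- which(sites$chrom[cols] == sw$chrom &
                            sites$pos[cols] - 1L >= sw$start &
                            sites$pos[cols] - 1L < sw$end)
          if (!length(swcols)) next
          fixed <- swcols[stats::runif(length(swcols)) > sw$rho_sweep]
          founders[, fixed] <- rep(founders[1, fixed], each = H)
        }
        gaps <- diff(sites$pos[cols])
        p_sw <- 1 - exp(-config$copy_switch_rate * gaps)
        for (i in rows) {
          gsum <- integer(length(cols))
          for (h in 1:2) {
            # founder index is piecewise constant between switch points
            seg <- cumsum(c(TRUE, stats::runif(length(p_sw)) < p_sw))
            idx <- sample.int(H, max(seg), replace = TRUE)[seg]
            gsum <- gsum + founders[cbind(idx, seq_along(cols))]
          }
          dosage[i, cols] <- gsum
        }
      }
    }
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < config$missing_rate
    dosage[mask] <- NA_integer_
  }
  rownames(dosage) <- ids
  g <- genotype_matrix(dosage, sites[, c("chrom", "pos", "ref", "alt")],
                       subpop = stats::setNames(pops, ids))
  g$sites$region <- sites$region

  # ---- phenotypes ----------------------------------------------------------
  n_t <- length(config$timepoints)
  dos_c <- dosage
  cm <- colMeans(dos_c, na.rm = TRUE)
  nafill <- which(is.na(dos_c), arr.ind = TRUE)
  if (nrow(nafill)) dos_c[nafill] <- cm[nafill[, 2]]

  std <- function(v) {
    s <- stats::sd(v)
    if (s < 1e-12) stop("planted locus is monomorphic; cannot reach target PVE")
    (v - mean(v)) / s
  }
  # resolve unset planted loci to common sites (so target PVE is reachable
  # and the locus survives downstream MAF filtering)
  maf_real <- { pbar <- colMeans(dos_c) / 2; pmin(pbar, 1 - pbar) }
  used <- unlist(lapply(qtns, `[[`, "site"))
  used <- used[!is.na(used)]
  pick_site <- function(min_maf) {
    elig <- setdiff(which(maf_real >= min_maf), used)
    if (!length(elig)) stop("no eligible site with MAF >= ", min_maf,
                            " for a planted locus")
    s <- if (length(elig) == 1) elig else sample(elig, 1)
    used <<- c(used, s)
    s
  }
  for (i in seq_along(qtns))
    if (is.na(qtns[[i]]$site))
      qtns[[i]]$site <- pick_site(qtns[[i]]$min_maf)
  for (i in seq_along(epi_pairs)) {
    mm <- epi_pairs[[i]]$min_maf
    if (is.na(epi_pairs[[i]]$siteA)) epi_pairs[[i]]$siteA <- pick_site(mm)
    if (is.na(epi_pairs[[i]]$siteB)) epi_pairs[[i]]$siteB <- pick_site(mm)
  }

  K <- ibs_kinship(dos_c)
  L <- t(chol(K + diag(1e-6, n)))

  pheno <- NULL
  truth_eff <- NULL
  for (tr in config$traits) {
    upoly <- std(as.vector(L %*% stats::rnorm(n)))
    comp <- list()   # list of list(u=vector, pve=per-timepoint, label)
    for (qi in seq_along(qtns)) {
      q <- qtns[[qi]]
      if (q$trait != tr) next
      x <- dos_c[, q$site]
      wd <- as.numeric(x == 1)
      r <- q$dom_ratio
      pa <- if (is.infinite(r)) 0 else q$pve / (1 + r)
      pd <- if (is.infinite(r)) q$pve else q$pve * r / (1 + r)
      if (pa > 0)
        comp[[length(comp) + 1]] <- list(
          u = std(x), pve = pve_trajectory(pa, q$pve_class, n_t),
          label = paste0("qtn", qi, "_a"), site = q$site, kind = "additive",
          scale = 1 / stats::sd(x))
      if (pd > 0)
        comp[[length(comp) + 1]] <- list(
          u = std(wd), pve = pve_trajectory(pd, q$pve_class, n_t),
          label = paste0("qtn", qi, "_d"), site = q$site, kind = "dominance",
          scale = 1 / stats::sd(wd))
    }
    for (ei in seq_along(epi_pairs)) {
      ep <- epi_pairs[[ei]]
      if (ep$trait != tr) next
      wa <- function(x) x - 1
      wd <- function(x) as.numeric(x == 1) - 0.5
      fA <- if (substr(ep$type, 1, 1) == "a") wa else wd
      fB <- if (substr(ep$type, 3, 3) == "a") wa else wd
      comp[[length(comp) + 1]] <- list(
        u = std(fA(dos_c[, ep$siteA]) * fB(dos_c[, ep$siteB])),
        pve = pve_trajectory(ep$pve, ep$pve_class, n_t),
        label = paste0("epi", ei), site = NA, kind = ep$type, scale = NA)
    }
    pve_mat <- if (length(comp))
      sapply(comp, `[[`, "pve") else matrix(0, n_t, 0)
    if (is.null(dim(pve_mat))) pve_mat <- matrix(pve_mat, n_t)
    # keep the polygenic term orthogonal to the planted components so each
    # planted locus explains its target variance fraction in-sample
    if (length(comp)) {
      U <- sapply(comp, `[[`, "u")
      upoly <- std(stats::lm.fit(cbind(1, U), upoly)$residuals)
    }
    tot <- rowSums(pve_mat) + config$h2_poly
    if (any(tot >= 1))
      stop("summed target PVE (incl. polygenic) must be < 1 for trait ", tr)
    Y <- matrix(stats::rnorm(n * n_t), n, n_t)
    Y <- sweep(Y, 2, sqrt(1 - tot), `*`) +
      outer(upoly, rep(sqrt(config$h2_poly), n_t))
    for (ci in seq_along(comp))
      Y <- Y + outer(comp[[ci]]$u, sqrt(pve_mat[, ci]))
    pheno <- rbind(pheno,
                   data.frame(individual = rep(ids, n_t), trait = tr,
                              timepoint = rep(config$timepoints, each = n),
                              value = as.vector(Y), stringsAsFactors = FALSE))
    for (ci in seq_along(comp))
      truth_eff <- rbind(truth_eff, data.frame(
        label = comp[[ci]]$label, trait = tr,
        timepoint = config$timepoints, kind = comp[[ci]]$kind,
        site = comp[[ci]]$site,
        pve = pve_mat[, ci],
        effect = sqrt(pve_mat[, ci]) * comp[[ci]]$scale,
        stringsAsFactors = FALSE))
  }

  truth <- list(
    regions = regions,
    freq = freq,
    qtns = lapply(qtns, unclass),
    sweeps = lapply(sweeps, unclass),
    epi_pairs = lapply(epi_pairs, unclass),
    effects = truth_eff,
    seed = config$seed)
  list(genotypes = g, phenotypes = pheno, truth = truth)
}

# ---- toy gene models -------------------------------------------------------

#' Simulate toy gene models with a reference sequence
#'
#' Places non-overlapping protein-coding genes (5'UTR, CDS exons with
#' consistent frames, intron, 3'UTR; random strand) and a few ncRNA records
#' (lncRNA / pre-miRNA) on a random DNA sequence. CDS lengths are always
#' divisible by 3.
#'
#' @param n_genes number of protein-coding genes.
#' @param region_length sequence length in bp.
#' @param chrom chromosome name.
#' @param n_ncrna number of ncRNA records.
#' @param seed RNG seed.
#' @return object of class `gene_model_set`: data.frames `genes`, `exons`,
#'   `cds` (with `frame`), `ncrna`, plus `seq` (named character vector of the
#'   reference sequence) and `chrom`. Coordinates 0-based half-open.
#' @export
simulate_gene_models <- function(n_genes, region_length = 50000L,
                                 chrom = "Chr01", n_ncrna = 2L, seed = 1L) {
  set.seed(seed)
  slot_len <- region_length %/% max(1L, (n_genes + n_ncrna))
  if (slot_len < 2500)
    stop("region too short for ", n_genes + n_ncrna, " features")
  feats <- sample(c(rep("gene", n_genes), rep("ncrna", n_ncrna)))
  genes <- exons <- cds <- ncrna <- NULL
  gi <- ni <- 0L
  for (k in seq_along(feats)) {
    base <- (k - 1L) * slot_len + sample.int(200L, 1)
    if (feats[k] == "gene") {
      gi <- gi + 1L
      id <- sprintf("gene%02d", gi)
      strand <- sample(c("+", "-"), 1)
      utr5 <- sample(80:150, 1)
      cds1 <- 3L * sample(60:120, 1)
      intron <- sample(120:300, 1)
      cds2 <- 3L * sample(40:90, 1)
      utr3 <- sample(80:150, 1)
      # layout left-to-right in genomic coordinates
      b <- base
      seg <- cumsum(c(0, utr5, cds1, intron, cds2, utr3)) + b
      genes <- rbind(genes, data.frame(
        gene_id = id, chrom = chrom, start = seg[1], end = seg[6],
        strand = strand, stringsAsFactors = FALSE))
      exons <- rbind(exons,
        data.frame(gene_id = id, start = c(seg[1], seg[4]),
                   end = c(seg[3], seg[6]), stringsAsFactors = FALSE))
      cds_df <- data.frame(gene_id = id, start = c(seg[2], seg[4]),
                           end = c(seg[3], seg[5]), stringsAsFactors = FALSE)
      # frame = (3 - preceding CDS length mod 3) mod 3 in translation order
      if (strand == "+") {
        cds_df$frame <- c(0L, (3L - (cds1 %% 3L)) %% 3L)
      } else {
        cds_df <- cds_df[2:1, ]
        cds_df$frame <- c(0L, (3L - (cds2 %% 3L)) %% 3L)
      }
      cds <- rbind(cds, cds_df)
    } else {
      ni <- ni + 1L
      len <- sample(200:800, 1)
      ncrna <- rbind(ncrna, data.frame(
        id = sprintf("ncrna%02d", ni), chrom = chrom,
        start = base, end = base + len,
        class = sample(c("lncRNA", "pre_miRNA"), 1),
        stringsAsFactors = FALSE))
    }
  }
  seq <- paste(sample(c("A", "C", "G", "T"), region_length, TRUE),
               collapse = "")
  structure(list(genes = genes, exons = exons, cds = cds,
                 ncrna = if (is.null(ncrna))
                   data.frame(id = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              class = character(0)) else ncrna,
                 seq = stats::setNames(seq, chrom), chrom = chrom,
                 region_length = as.integer(region_length)),
            class = "gene_model_set")
}

#' Write gene models to GFF3 (and optionally FASTA)
#'
#' @param gm a `gene_model_set`.
#' @param gff_path output GFF3 path.
#' @param fasta_path optional output FASTA path for the reference sequence.
#' @return `gff_path`, invisibly.
#' @export
write_gene_models <- function(gm, gff_path, fasta_path = NULL) {
  stopifnot(inherits(gm, "gene_model_set"))
  rows <- list()
  add <- function(start, end, type, id, strand = "*", parent = NA_character_,
                  phase = NA_integer_, class = NA_character_)
    rows[[length(rows) + 1]] <<- data.frame(
      start = start, end = end, type = type, ID = id, strand = strand,
      parent = parent, phase = phase, class = class,
      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gm$genes))) {
    gn <- gm$genes[i, ]
    add(gn$start, gn$end, "gene", gn$gene_id, gn$strand)
    ex <- gm$exons[gm$exons$gene_id == gn$gene_id, ]
    for (j in seq_len(nrow(ex)))
      add(ex$start[j], ex$end[j], "exon", paste0(gn$gene_id, ".e", j),
          gn$strand, gn$gene_id)
    cd <- gm$cds[gm$cds$gene_id == gn$gene_id, ]
    for (j in seq_len(nrow(cd)))
      add(cd$start[j], cd$end[j], "CDS", paste0(gn$gene_id, ".c", j),
          gn$strand, gn$gene_id, cd$frame[j])
  }
  for (i in seq_len(nrow(gm$ncrna))) {
    nc <- gm$ncrna[i, ]
    add(nc$start, nc$end, "ncRNA", nc$id, "*", class = nc$class)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(gm$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$parent), "", df$parent)
  gr$phase <- df$phase
  gr$ncrna_class <- df$class
  rtracklayer::export(gr, gff_path, format = "GFF3")
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(gm$seq), fasta_path)
  invisible(gff_path)
}

#' Read gene models from GFF3 (plus optional FASTA reference)
#'
#' Inverse of [write_gene_models()] for the feature types this package emits
#' (gene, exon, CDS, ncRNA).
#'
#' @param gff_path GFF3 path.
#' @param fasta_path optional FASTA with the reference sequence.
#' @return a `gene_model_set` (with `seq = NULL` when no FASTA given).
#' @export
read_gene_models <- function(gff_path, fasta_path = NULL) {
  gr <- rtracklayer::import(gff_path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   type = as.character(gr$type),
                   id = as.character(gr$ID),
                   stringsAsFactors = FALSE)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  phase <- if (!is.null(gr$phase)) as.integer(gr$phase) else
    rep(NA_integer_, length(gr))
  ncls <- if (!is.null(gr$ncrna_class)) as.character(gr$ncrna_class) else
    rep(NA_character_, length(gr))
  is_g <- df$type == "gene"
  genes <- data.frame(gene_id = df$id[is_g], chrom = df$chrom[is_g],
                      start = df$start[is_g], end = df$end[is_g],
                      strand = df$strand[is_g], stringsAsFactors = FALSE)
  is_e <- df$type == "exon"
  exons <- data.frame(gene_id = parent[is_e], start = df$start[is_e],
                      end = df$end[is_e], stringsAsFactors = FALSE)
  is_c <- df$type == "CDS"
  cds <- data.frame(gene_id = parent[is_c], start = df$start[is_c],
                    end = df$end[is_c], frame = phase[is_c],
                    stringsAsFactors = FALSE)
  is_n <- df$type == "ncRNA"
  ncrna <- data.frame(id = df$id[is_n], chrom = df$chrom[is_n],
                      start = df$start[is_n], end = df$end[is_n],
                      class = ncls[is_n], stringsAsFactors = FALSE)
  seq <- NULL
  chrom <- if (nrow(genes)) genes$chrom[1] else unique(df$chrom)[1]
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seq <- stats::setNames(as.character(ss), names(ss))
    chrom <- names(seq)[1]
  }
  structure(list(genes = genes, exons = exons, cds = cds, ncrna = ncrna,
                 seq = seq, chrom = chrom, region_length = NA_integer_),
            class = "gene_model_set")
}
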