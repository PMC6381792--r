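# QTL interval mapping on pseudo-testcross full-sib families.
#
# The scan is Haley-Knott regression: at each grid position the expected
# genotype score is computed from the flanking markers via Haldane
# recombination fractions, and the phenotype is regressed on that score
# (optionally with cofactor markers as covariates).
# LOD = (n/2) * log10(RSS0/RSS1); PVE = 1 - 10^(-2*LOD/n).

#' Build the test-position grid for a linkage map
#'
#' @param map linkage map data.frame (`lg`, `marker`, `cm`).
#' @param step grid step in cM (default 1).
#' @return data.frame with columns `lg`, `cm` (marker positions included).
#' @export
scan_grid <- function(map, step = 1) {
  out <- lapply(split(map, map$lg), function(mk) {
    cm <- sort(unique(c(seq(min(mk$cm), max(mk$cm), by = step), mk$cm)))
    data.frame(lg = unique(mk$lg), cm = cm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Expected genotype score P(class = 1 | flanking markers) at every grid
# position; individuals x positions. Missing flank calls fall back to the
# other flank alone, or 0.5 when both are missing.
genotype_scores <- function(data, grid) {
  Z <- matrix(NA_real_, nrow(data$calls), nrow(grid),
              dimnames = list(rownames(data$calls), NULL))
  for (l in unique(grid$lg)) {
    mk <- data$map[data$map$lg == l, ]
    mk <- mk[order(mk$cm), ]
    G <- data$calls[, mk$marker, drop = FALSE]
    gpos <- which(grid$lg == l)
    for (jj in gpos) {
      p <- grid$cm[jj]
      iL <- findInterval(p, mk$cm)               # largest cm <= p
      at_marker <- iL >= 1 && mk$cm[iL] == p
      if (at_marker) {
        z <- as.numeric(G[, iL])
        na <- is.na(z)
        if (any(na)) {
          iLm <- if (iL > 1) iL - 1L else NA
          iRm <- if (iL < nrow(mk)) iL + 1L else NA
          z[na] <- flank_score(p, mk$cm, G, iLm, iRm)[na]
        }
      } else {
        iR <- iL + 1L
        if (iL < 1) { iLx <- NA; iRx <- iR } else { iLx <- iL; iRx <-
          if (iR <= nrow(mk)) iR else NA }
        z <- flank_score(p, mk$cm, G, iLx, iRx)
      }
      Z[, jj] <- z
    }
  }
  Z
}

# conditional class-1 probability from (possibly missing) flanks iL, iR
flank_score <- function(p, cm, G, iL, iR) {
  n <- nrow(G)
  gL <- if (!is.na(iL)) as.numeric(G[, iL]) else rep(NA_real_, n)
  gR <- if (!is.na(iR)) as.numeric(G[, iR]) else rep(NA_real_, n)
  rL <- if (!is.na(iL)) haldane_r(p - cm[iL]) else NA_real_
  rR <- if (!is.na(iR)) haldane_r(cm[iR] - p) else NA_real_
  pL1 <- gL * (1 - rL) + (1 - gL) * rL            # P(Q=1 | gL)
  pRg1 <- gR * (1 - rR) + (1 - gR) * rR           # P(gR | Q=1)
  pRg0 <- gR * rR + (1 - gR) * (1 - rR)           # P(gR | Q=0)
  both <- !is.na(gL) & !is.na(gR)
  onlyL <- !is.na(gL) & is.na(gR)
  onlyR <- is.na(gL) & !is.na(gR)
  z <- rep(0.5, n)
  z[both] <- pL1[both] * pRg1[both] /
    (pL1[both] * pRg1[both] + (1 - pL1[both]) * pRg0[both])
  z[onlyL] <- pL1[onlyL]
  pR1 <- gR * (1 - rR) + (1 - gR) * rR            # P(Q=1 | gR)
  z[onlyR] <- pR1[onlyR]
  z
}

# LOD profile of y on columns of Z after projecting out `covar` (with
# intercept). Returns NA where the residualized score is constant.
lod_profile <- function(Z, y, covar = NULL) {
  ok <- !is.na(y)
  if (!is.null(covar)) {
    covar <- as.matrix(covar)
    ok <- ok & stats::complete.cases(covar)
  }
  y <- y[ok]
  Z <- Z[ok, , drop = FALSE]
  n <- length(y)
  X0 <- if (is.null(covar)) matrix(1, n, 1) else cbind(1, covar[ok, , drop = FALSE])
  q <- qr(X0)
  ry <- qr.resid(q, y)
  rz <- qr.resid(q, Z)
  sy <- sqrt(sum(ry^2))
  sz <- sqrt(colSums(rz^2))
  r2 <- (as.vector(crossprod(rz, ry)) / (sy * sz))^2
  r2[sz < 1e-10] <- NA_real_          # monomorphic flanks: position skipped
  if (sy < 1e-10) r2[] <- 0           # constant phenotype: no evidence
  r2 <- pmin(r2, 1 - 1e-12)
  lod <- -(n / 2) * log10(1 - r2)
  list(lod = lod, n = n)
}

#' Interval-mapping QTL scan for one phenotype set
#'
#' Haley-Knott regression at each grid position, with optional cofactor
#' markers as covariates. Cofactors lying within `exclusion_cm` of the test
#' position (same LG) are dropped from the covariate set at that position.
#' Peaks with LOD at or above `threshold` are reported with 1-LOD support
#' intervals.
#'
#' @param data a `linkage_dataset`.
#' @param trait,timepoint the phenotype set to scan.
#' @param cofactors character vector of cofactor marker names.
#' @param step grid step in cM.
#' @param threshold LOD reporting cut-off (default 3).
#' @param exclusion_cm cofactor exclusion window around the test position.
#' @return object of class `qtl_scan`: `grid` (lg, cm, lod, pve), `qtl`
#'   (peak records with support intervals), `trait`, `timepoint`, `n`,
#'   `cofactors`.
#' @export
interval_scan <- function(data, trait, timepoint, cofactors = character(0),
                          step = 1, threshold = 3, exclusion_cm = 10) {
  stopifnot(inherits(data, "linkage_dataset"))
  y <- phenotype_vector(data, trait, timepoint)
  if (sum(!is.na(y)) < 50)
    stop("phenotype present for fewer than 50 progeny in set ",
         trait, ":", timepoint)
  grid <- scan_grid(data$map, step)
  Z <- genotype_scores(data, grid)
  lod <- rep(NA_real_, nrow(grid))
  if (length(cofactors)) {
    stopifnot(all(cofactors %in% data$map$marker))
    C <- data$calls[, cofactors, drop = FALSE]
    C <- apply(C, 2, function(v) { v[is.na(v)] <- mean(v, na.rm = TRUE); v })
    C <- matrix(C, nrow = nrow(data$calls),
                dimnames = list(rownames(data$calls), cofactors))
    co_lg <- data$map$lg[match(cofactors, data$map$marker)]
    co_cm <- data$map$cm[match(cofactors, data$map$marker)]
    excl_key <- vapply(seq_len(nrow(grid)), function(j) {
      drop <- co_lg == grid$lg[j] & abs(co_cm - grid$cm[j]) < exclusion_cm
      paste(which(!drop), collapse = ",")
    }, character(1))
    nval <- NA_integer_
    for (key in unique(excl_key)) {
      cols <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1]]) else integer(0)
      jj <- which(excl_key == key)
      pr <- lod_profile(Z[, jj, drop = FALSE], y,
                        if (length(cols)) C[, cols, drop = FALSE] else NULL)
      lod[jj] <- pr$lod
      nval <- pr$n
    }
    n <- nval
  } else {
    pr <- lod_profile(Z, y)
    lod <- pr$lod
    n <- pr$n
  }
  grid$lod <- lod
  grid$pve <- 1 - 10^(-2 * lod / n)
  res <- structure(list(grid = grid, trait = trait, timepoint = timepoint,
                        n = n, cofactors = cofactors, threshold = threshold,
                        markers = split(data$map$cm, data$map$lg)),
                   class = "qtl_scan")
  res$qtl <- find_qtl_peaks(res, threshold)
  res
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("qtl_scan %s:%s  n=%d  max LOD=%.2f  QTL(LOD>=%.1f): %d\n",
              x$trait, x$timepoint, x$n, max(x$grid$lod, na.rm = TRUE),
              x$threshold, nrow(x$qtl)))
  invisible(x)
}

# peak extraction: one QTL per supra-threshold run, plus secondary peaks
# separated from every accepted peak by a valley >= `peakdrop` LOD below the
# smaller peak (shoulders of one QTL are never double-counted)
find_qtl_peaks <- function(scan, threshold = 3, peakdrop = 1) {
  out <- NULL
  for (l in unique(scan$grid$lg)) {
    gg <- scan$grid[scan$grid$lg == l, ]
    lod <- ifelse(is.na(gg$lod), -Inf, gg$lod)
    above <- which(lod >= threshold)
    if (!length(above)) next
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    for (run in runs) {
      ord <- run[order(-lod[run])]
      acc <- integer(0)
      for (cand in ord) {
        shoulder <- FALSE
        for (a in acc) {
          rng <- seq(min(cand, a), max(cand, a))
          if (min(lod[rng]) > lod[cand] - peakdrop) { shoulder <- TRUE; break }
        }
        if (!shoulder) acc <- c(acc, cand)
      }
      for (pk in sort(acc)) {
        ci <- drop_interval(gg$cm, gg$lod, pk, drop = 1,
                            marker_cm = scan$markers[[l]])
        out <- rbind(out, data.frame(
          lg = l, peak_cm = gg$cm[pk], lod = gg$lod[pk], pve = gg$pve[pk],
          ci_lo = ci[1], ci_hi = ci[2],
          trait = scan$trait, timepoint = scan$timepoint,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(lg = character(0), peak_cm = numeric(0),
                      lod = numeric(0), pve = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      trait = character(0), timepoint = character(0),
                      stringsAsFactors = FALSE)
  out
}

# maximal interval around peak index where LOD >= LOD[pk] - drop, expanded
# to the first grid position outside the drop region and then to the nearest
# flanking markers (between-marker positions are likelihood interpolation in
# Haley-Knott regression, so an endpoint between markers overstates the
# resolution), clipped to the LG ends
drop_interval <- function(cm, lod, pk, drop = 1, marker_cm = NULL) {
  cut <- lod[pk] - drop
  lo <- pk
  while (lo > 1 && !is.na(lod[lo - 1]) && lod[lo - 1] >= cut) lo <- lo - 1
  hi <- pk
  while (hi < length(lod) && !is.na(lod[hi + 1]) && lod[hi + 1] >= cut)
    hi <- hi + 1
  if (lo > 1) lo <- lo - 1
  if (hi < length(lod)) hi <- hi + 1
  out <- c(cm[lo], cm[hi])
  if (!is.null(marker_cm)) {
    left <- marker_cm[marker_cm <= out[1]]
    right <- marker_cm[marker_cm >= out[2]]
    out[1] <- if (length(left)) max(left) else cm[1]
    out[2] <- if (length(right)) min(right) else cm[length(cm)]
  }
  out
}

#' One-LOD support interval around a scan peak
#'
#' @param scan a `qtl_scan`.
#' @param lg linkage group of the peak.
#' @param peak_cm peak position in cM (nearest grid point used).
#' @param drop LOD drop defining the interval (default 1).
#' @return numeric `c(lo, hi)` in cM, clipped to the LG ends.
#' @export
support_interval <- function(scan, lg, peak_cm, drop = 1) {
  gg <- scan$grid[scan$grid$lg == lg, ]
  pk <- which.min(abs(gg$cm - peak_cm))
  drop_interval(gg$cm, gg$lod, pk, drop, marker_cm = scan$markers[[lg]])
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype against the genotypes `n_perm` times, records the
#' genome-wide maximum LOD of each permutation scan, and returns its
#' `(1 - alpha)` quantile.
#'
#' @inheritParams interval_scan
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed RNG seed.
#' @return the LOD threshold (attribute `max_lods` holds the null maxima).
#' @export
permutation_threshold <- function(data, trait, timepoint, n_perm = 1000,
                                  alpha = 0.05, step = 1, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives unstable thresholds")
  set.seed(seed)
  y <- phenotype_vector(data, trait, timepoint)
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  grid <- scan_grid(data$map, step)
  Z <- genotype_scores(data, grid)[ok, , drop = FALSE]
  Zc <- scale(Z)                          # center+scale once
  keep <- which(!is.na(colSums(Zc)) & apply(Z, 2, stats::sd) > 1e-10)
  Zc <- Zc[, keep, drop = FALSE]
  P <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) P[, b] <- sample(y)
  Pc <- scale(P)
  R <- crossprod(Zc, Pc) / (n - 1)        # positions x permutations
  R2 <- pmin(R^2, 1 - 1e-12)
  maxlod <- apply(-(n / 2) * log10(1 - R2), 2, max)
  thr <- stats::quantile(maxlod, 1 - alpha, names = FALSE)
  attr(thr, "max_lods") <- maxlod
  thr
}

#' Multiple-QTL cofactor scan
#'
#' Iterative cofactor scheme: run an initial interval scan, take the nearest
#' marker to each peak as a cofactor candidate, keep candidates whose partial
#' regression P-value is below `p_cofactor`, rescan with the retained
#' cofactors, and repeat until the cofactor set is stable (at most
#' `max_iter` iterations).
#'
#' @inheritParams interval_scan
#' @param p_cofactor retention P-value for cofactors (default 0.02).
#' @param max_iter maximum iterations (default 10).
#' @return a `qtl_scan` with elements `cofactors` (final set), `iterations`,
#'   and `converged`.
#' @export
mqm_scan <- function(data, trait, timepoint, step = 1, threshold = 3,
                     p_cofactor = 0.02, max_iter = 10, exclusion_cm = 10) {
  scan <- interval_scan(data, trait, timepoint, step = step,
                        threshold = threshold, exclusion_cm = exclusion_cm)
  cof <- character(0)
  seen <- list(character(0))
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    cand <- unique(c(cof, nearest_markers(data$map, scan$qtl)))
    cof_new <- retain_cofactors(data, trait, timepoint, cand, p_cofactor)
    if (setequal(cof_new, cof)) { converged <- TRUE; break }
    if (any(vapply(seen, function(s) setequal(s, cof_new), logical(1)))) {
      cof <- cof_new      # oscillation: stop, flagged below
      break
    }
    seen[[length(seen) + 1]] <- cof_new
    cof <- cof_new
    scan <- interval_scan(data, trait, timepoint, cofactors = cof,
                          step = step, threshold = threshold,
                          exclusion_cm = exclusion_cm)
  }
  scan$cofactors <- cof
  scan$iterations <- iterations
  scan$converged <- converged
  scan
}

# per-coefficient two-sided t-test P-values of an OLS fit (X includes any
# intercept column); NA for aliased coefficients
wald_p_lm <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  n <- length(y)
  keep <- !is.na(fit$coefficients)
  sigma2 <- sum(fit$residuals^2) / (n - p)
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  covb <- chol2inv(R) * sigma2
  se <- sqrt(diag(covb))
  pv <- rep(NA_real_, ncol(X))
  pv[fit$qr$pivot[seq_len(p)]] <-
    2 * stats::pt(abs(fit$coefficients[fit$qr$pivot[seq_len(p)]] / se),
                  df = n - p, lower.tail = FALSE)
  names(pv) <- colnames(X)
  pv
}

nearest_markers <- function(map, qtl) {
  if (nrow(qtl) == 0) return(character(0))
  vapply(seq_len(nrow(qtl)), function(i) {
    mk <- map[map$lg == qtl$lg[i], ]
    mk$marker[which.min(abs(mk$cm - qtl$peak_cm[i]))]
  }, character(1))
}

retain_cofactors <- function(data, trait, timepoint, cand, p_cofactor) {
  if (!length(cand)) return(character(0))
  y <- phenotype_vector(data, trait, timepoint)
  C <- data$calls[, cand, drop = FALSE]
  C <- apply(C, 2, function(v) { v[is.na(v)] <- mean(v, na.rm = TRUE); v })
  C <- matrix(C, nrow = nrow(data$calls), dimnames = list(NULL, cand))
  ok <- !is.na(y)
  X <- cbind(`(Intercept)` = 1, C[ok, , drop = FALSE])
  pv <- wald_p_lm(X, y[ok])[-1]
  cand[!is.na(pv) & pv < p_cofactor]
}

#' Cluster co-localised QTL into discrete overlap regions
#'
#' Single-linkage clustering of QTL records (across traits and timepoints):
#' two QTL join the same region when they lie on the same LG, their support
#' intervals overlap, and their peaks are less than `max_peak_dist` cM apart.
#'
#' @param qtls data.frame of QTL records (columns `lg`, `peak_cm`, `ci_lo`,
#'   `ci_hi`, `trait`, `timepoint`), e.g. rbind of `qtl_scan$qtl` tables.
#' @param max_peak_dist peak-distance criterion in cM (default 1.0).
#' @return data.frame of overlap regions: `region`, `lg`, `cm_lo`, `cm_hi`,
#'   `n_qtl`, `sets` (trait:timepoint coverage); member assignment is
#'   returned in attribute `membership`.
#' @export
cluster_colocalized <- function(qtls, max_peak_dist = 1.0) {
  if (nrow(qtls) == 0)
    return(data.frame(region = character(0), lg = character(0),
                      cm_lo = numeric(0), cm_hi = numeric(0),
                      n_qtl = integer(0), sets = character(0),
                      stringsAsFactors = FALSE))
  n <- nrow(qtls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (qtls$lg[i] != qtls$lg[j]) next
    overlap <- qtls$ci_lo[i] <= qtls$ci_hi[j] & qtls$ci_lo[j] <= qtls$ci_hi[i]
    close <- abs(qtls$peak_cm[i] - qtls$peak_cm[j]) < max_peak_dist
    if (overlap && close) parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ids <- match(comp, unique(comp))
  regions <- do.call(rbind, lapply(split(seq_len(n), ids), function(ix) {
    data.frame(lg = qtls$lg[ix[1]],
               cm_lo = min(qtls$ci_lo[ix]), cm_hi = max(qtls$ci_hi[ix]),
               n_qtl = length(ix),
               sets = paste(sort(unique(paste0(qtls$trait[ix], ":",
                                               qtls$timepoint[ix]))),
                            collapse = ","),
               stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$lg, regions$cm_lo), , drop = FALSE]
  regions <- cbind(region = sprintf("OR%02d", seq_len(nrow(regions))),
                   regions, stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  attr(regions, "membership") <- ids
  regions
}

#' Permutation test for QTL hotspots
#'
#' Counts QTL peaks per cM bin across the map, builds a null by redistributing
#' all peaks uniformly over the total map length `n_perm` times, and flags
#' bins whose observed count exceeds the `(1 - alpha)` quantile of the null
#' genome-wide maximum per-bin count (FWER-controlling). `per_bin = TRUE`
#' instead uses the pooled per-bin null count quantile.
#'
#' @param qtls QTL record data.frame (needs `lg`, `peak_cm`).
#' @param map linkage map (defines LG lengths), or a named numeric vector of
#'   LG lengths in cM.
#' @param n_perm permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param bin_cm bin width (default 1 cM).
#' @param per_bin use the pooled per-bin null instead of the max-count null.
#' @param seed RNG seed.
#' @return object of class `hotspot_result`: `bins` (lg, cm_lo, cm_hi, count,
#'   hotspot flag), `threshold`, `n_perm`, `alpha`.
#' @export
hotspot_test <- function(qtls, map, n_perm = 1000, alpha = 0.05, bin_cm = 1,
                         per_bin = FALSE, seed = 1L) {
  set.seed(seed)
  lg_len <- if (is.data.frame(map))
    vapply(split(map$cm, map$lg), max, numeric(1)) else map
  edges <- lapply(lg_len, function(L) seq(0, ceiling(L / bin_cm) * bin_cm,
                                          by = bin_cm))
  bins <- do.call(rbind, lapply(names(edges), function(l)
    data.frame(lg = l, cm_lo = utils::head(edges[[l]], -1),
               cm_hi = utils::tail(edges[[l]], -1),
               stringsAsFactors = FALSE)))
  bins$count <- 0L
  n_qtl <- nrow(qtls)
  if (n_qtl > 0) {
    key <- paste0(qtls$lg, "@",
                  pmin(floor(qtls$peak_cm / bin_cm),
                       floor((lg_len[qtls$lg] - 1e-9) / bin_cm)))
    bk <- paste0(bins$lg, "@", bins$cm_lo / bin_cm)
    tb <- table(key)
    bins$count[match(names(tb), bk)] <- as.integer(tb)
  }
  total <- sum(unlist(lapply(lg_len, function(L) ceiling(L / bin_cm))))
  if (n_qtl <= 1) {
    bins$hotspot <- FALSE
    return(structure(list(bins = bins, threshold = Inf, n_perm = n_perm,
                          alpha = alpha), class = "hotspot_result"))
  }
  null_stat <- numeric(n_perm)
  pooled <- if (per_bin) integer(0) else NULL
  for (b in seq_len(n_perm)) {
    cnt <- tabulate(sample.int(total, n_qtl, replace = TRUE), nbins = total)
    if (per_bin) pooled <- c(pooled, cnt) else null_stat[b] <- max(cnt)
  }
  thr <- if (per_bin) stats::quantile(pooled, 1 - alpha, names = FALSE)
  else stats::quantile(null_stat, 1 - alpha, names = FALSE)
  bins$hotspot <- bins$count > thr
  structure(list(bins = bins, threshold = thr, n_perm = n_perm,
                 alpha = alpha), class = "hotspot_result")
}

#' @export
print.hotspot_result <- function(x, ...) {
  cat(sprintf("hotspot_test: %d bins, threshold count %.1f, %d hotspot bin(s)\n",
              nrow(x$bins), x$threshold, sum(x$bins$hotspot)))
  invisible(x)
}
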