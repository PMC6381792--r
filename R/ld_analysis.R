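# Pairwise composite LD (dosage-correlation r^2) with permutation P-values,
# high-LD block detection on ordered sites, and Hill-Weir decay fits.

#' Pairwise r-squared with permutation P-values
#'
#' Composite LD: squared Pearson correlation of dosage vectors over
#' complete-case individuals per pair. The permutation P-value is the
#' plus-one-corrected fraction of label permutations reaching the observed
#' r-squared. Sites below `min_maf` are excluded; pairs with fewer than
#' `min_complete` complete cases are skipped.
#'
#' @param g a `genotype_matrix`.
#' @param sites optional site selection (indices into `g$sites` or ids);
#'   default: all sites.
#' @param n_perm permutations per pair (default 1000; production runs use
#'   1e5); 0 skips the permutation test (P = NA).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @param min_complete minimum complete cases per pair (default 10).
#' @param max_pairs optional cap: only pairs within this many ordered sites
#'   of each other are tested (NULL = all pairs).
#' @param seed RNG seed.
#' @return object of class `ld_result`: `pairs` data.frame (`idA`, `idB`,
#'   `posA`, `posB`, `dist`, `r2`, `p`), `sites` (the retained site table),
#'   `n` (panel size).
#' @export
pairwise_r2 <- function(g, sites = NULL, n_perm = 1000, min_maf = 0.05,
                        min_complete = 10, max_pairs = NULL, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  set.seed(seed)
  ix <- if (is.null(sites)) seq_len(ncol(g$dosage))
  else if (is.character(sites)) match(sites, g$sites$id)
  else sites
  maf <- site_maf(g)[ix]
  ix <- ix[!is.na(maf) & maf >= min_maf]
  st <- g$sites[ix, , drop = FALSE]
  o <- order(st$chrom, st$pos)
  ix <- ix[o]; st <- st[o, , drop = FALSE]
  m <- length(ix)
  D <- g$dosage[, ix, drop = FALSE]
  # one shared set of label permutations per complete-case count (marginal
  # permutation P-values do not require fresh permutations per pair)
  perm_cache <- new.env(parent = emptyenv())
  perm_idx <- function(n) {
    key <- as.character(n)
    if (is.null(perm_cache[[key]]))
      perm_cache[[key]] <- vapply(seq_len(n_perm), function(b) sample.int(n),
                                  integer(n))
    perm_cache[[key]]
  }
  rows <- list()
  for (i in seq_len(max(0, m - 1))) {
    jmax <- if (is.null(max_pairs)) m else min(m, i + max_pairs)
    for (j in seq(i + 1, length.out = max(0, jmax - i))) {
      if (st$chrom[j] != st$chrom[i]) next
      ok <- !is.na(D[, i]) & !is.na(D[, j])
      nok <- sum(ok)
      if (nok < min_complete) next
      x <- D[ok, i]; y <- D[ok, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r2 <- stats::cor(x, y)^2
      p <- NA_real_
      if (n_perm > 0) {
        xc <- x - mean(x); yc <- y - mean(y)
        denom2 <- sum(xc^2) * sum(yc^2)
        Yp <- matrix(yc[perm_idx(nok)], nok, n_perm)
        r2p <- drop(crossprod(xc, Yp))^2 / denom2
        p <- (1 + sum(r2p >= r2)) / (n_perm + 1)
      }
      rows[[length(rows) + 1]] <- list(
        idA = st$id[i], idB = st$id[j], posA = st$pos[i], posB = st$pos[j],
        dist = abs(st$pos[j] - st$pos[i]), r2 = r2, p = p)
    }
  }
  pairs <- if (length(rows)) {
    do.call(rbind.data.frame,
            c(rows, list(stringsAsFactors = FALSE, make.row.names = FALSE)))
  } else
    data.frame(idA = character(0), idB = character(0), posA = integer(0),
               posB = integer(0), dist = integer(0), r2 = numeric(0),
               p = numeric(0), stringsAsFactors = FALSE)
  structure(list(pairs = pairs, sites = st, n = nrow(g$dosage),
                 n_perm = n_perm), class = "ld_result")
}

#' Detect high-LD blocks
#'
#' Maximal runs of consecutive (position-ordered) sites in which every
#' within-run pair satisfies `r2 >= r2_min` and `p <= p_max`. Runs of at
#' least 2 sites are reported with their bp span.
#'
#' @param ld an `ld_result` from [pairwise_r2()].
#' @param r2_min minimum pairwise r-squared (default 0.75).
#' @param p_max maximum permutation P (default 1e-3; ignored when the pair
#'   table has no P-values).
#' @return data.frame of blocks: `block`, `chrom`, `start`, `end` (0-based
#'   half-open bp span), `n_sites`, `sites` (comma-joined ids).
#' @export
detect_blocks <- function(ld, r2_min = 0.75, p_max = 1e-3) {
  stopifnot(inherits(ld, "ld_result"))
  st <- ld$sites
  key <- paste(ld$pairs$idA, ld$pairs$idB)
  ok_pair <- function(a, b) {
    hit <- match(paste(a, b), key)
    if (is.na(hit)) hit <- match(paste(b, a), key)
    if (is.na(hit)) return(FALSE)
    r2ok <- ld$pairs$r2[hit] >= r2_min
    pok <- is.na(ld$pairs$p[hit]) || ld$pairs$p[hit] <= p_max
    r2ok && pok
  }
  blocks <- NULL
  i <- 1L
  m <- nrow(st)
  while (i < m) {
    j <- i
    while (j < m && st$chrom[j + 1] == st$chrom[i] &&
           all(vapply(i:j, function(k) ok_pair(st$id[k], st$id[j + 1]),
                      logical(1))))
      j <- j + 1L
    if (j > i)
      blocks <- rbind(blocks, data.frame(
        chrom = st$chrom[i], start = st$pos[i] - 1L, end = st$pos[j],
        n_sites = j - i + 1L,
        sites = paste(st$id[i:j], collapse = ","),
        stringsAsFactors = FALSE))
    i <- j + 1L
  }
  if (is.null(blocks))
    blocks <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), n_sites = integer(0),
                         sites = character(0), stringsAsFactors = FALSE)
  cbind(block = if (nrow(blocks)) sprintf("B%03d", seq_len(nrow(blocks)))
        else character(0), blocks, stringsAsFactors = FALSE)
}

#' Hill-Weir expected r-squared
#'
#' Drift-recombination expectation of r-squared at scaled recombination
#' `C = rho * distance`, with the finite-sample correction for `n`
#' haplotypes/individuals sampled.
#'
#' @param dist distance in bp.
#' @param rho recombination-scale parameter (per bp).
#' @param n sample size.
#' @return expected r-squared.
#' @export
hill_weir_r2 <- function(dist, rho, n) {
  C <- rho * dist
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD-decay curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the Hill-Weir expectation
#' against observed pair r-squared vs distance; reports the fitted `rho` and
#' the distance at which the fitted curve crosses `r2_target`.
#'
#' @param ld an `ld_result`, or a data.frame with `dist` and `r2`.
#' @param n sample size for the Hill-Weir correction (taken from the
#'   `ld_result` if available).
#' @param r2_target the crossing level to report (default 0.2).
#' @return list: `rho`, `decay_dist` (NA with `decay_note` when the curve
#'   does not cross within the data range), `fitted` function, `n_pairs`.
#' @export
fit_decay <- function(ld, n = NULL, r2_target = 0.2) {
  pairs <- if (inherits(ld, "ld_result")) ld$pairs else ld
  if (is.null(n)) n <- if (inherits(ld, "ld_result")) ld$n else
    stop("sample size n required")
  pairs <- pairs[!is.na(pairs$r2) & pairs$dist > 0, , drop = FALSE]
  if (nrow(pairs) < 50)
    warning("fewer than 50 pairs; decay fit will be unstable")
  if (nrow(pairs) >= 2 &&
      max(pairs$dist) / max(1, min(pairs$dist)) < 10)
    warning("pairs span less than a 10-fold distance range")
  start_rho <- 1 / stats::median(pairs$dist)
  fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ hill_weir_r2(dist, rho, n),
                      data = pairs, start = list(rho = start_rho),
                      lower = 1e-12, upper = 10,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("LD-decay fit failed to converge: ",
                             conditionMessage(e), " (n_pairs=", nrow(pairs),
                             ", start rho=", signif(start_rho, 3), ")"))
  rho <- stats::coef(fit)[["rho"]]
  f <- function(d) hill_weir_r2(d, rho, n)
  dr <- range(pairs$dist)
  decay <- NA_real_
  note <- NULL
  if (f(dr[1]) <= r2_target) {
    decay <- dr[1]
    note <- "curve below target at the shortest observed distance"
  } else if (f(dr[2]) > r2_target) {
    note <- "beyond data range"
  } else {
    decay <- stats::uniroot(function(d) f(d) - r2_target, dr)$root
  }
  list(rho = rho, decay_dist = decay, decay_note = note, fitted = f,
       n_pairs = nrow(pairs), r2_target = r2_target)
}
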