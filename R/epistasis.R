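# Two-locus epistasis: fixed-effects partition of the 3x3 genotype-class
# table with a 4-df interaction F-test and orthogonal 1-df component
# contrasts (additive x additive, additive x dominance, dominance x
# additive, dominance x dominance), Kempthorne-style with weights from the
# observed genotype frequencies so the contrasts stay orthogonal under
# departures from HWE frequencies (the classical equal-frequency weighting
# is available for oracle checks). The phenotypic contribution is
# c = SS_interaction / SS_total.

# per-locus additive and dominance contrast vectors over scores {0,1,2},
# orthogonalized against the intercept (and each other) under weights f
locus_contrasts <- function(f) {
  x <- c(0, 1, 2)
  wa <- x - sum(f * x)
  h <- as.numeric(x == 1)
  hd <- h - sum(f * h)
  hd <- hd - sum(f * hd * wa) / sum(f * wa^2) * wa
  list(a = wa, d = hd)
}

#' Two-locus epistasis partition for one SNP pair
#'
#' Fits the two-way fixed-effects model on genotype classes. The overall
#' interaction test compares the full cell-mean model with the additive
#' (locus A + locus B factor) model; its sum of squares is then decomposed
#' into four orthogonal 1-df components. Requires at least `min_classes`
#' populated genotype classes with `min_per_class` individuals each.
#'
#' @param g a `genotype_matrix`.
#' @param phenotypes long phenotype data.frame.
#' @param trait,timepoint the phenotype set.
#' @param snpA,snpB site ids or column indices.
#' @param Q optional structure covariates (labels or matrix); the phenotype
#'   is residualized on them before partitioning.
#' @param weighting `"observed"` (extended model, default) or `"equal"`
#'   (classical Kempthorne weights, exact on balanced designs).
#' @param min_classes minimum populated classes (default 5).
#' @param min_per_class minimum individuals per populated class (default 2).
#' @return object of class `epistasis_record`: genotype-class `counts` and
#'   `means`, `ss_int`, `df_int`, `p_int`, `components` (data.frame with SS,
#'   F, P per component), `c` (= SS_int / SS_total), `n`.
#' @export
two_locus_partition <- function(g, phenotypes, trait, timepoint, snpA, snpB,
                                Q = NULL, weighting = c("observed", "equal"),
                                min_classes = 5L, min_per_class = 2L) {
  weighting <- match.arg(weighting)
  ids <- rownames(g$dosage)
  jA <- if (is.character(snpA)) match(snpA, g$sites$id) else snpA
  jB <- if (is.character(snpB)) match(snpB, g$sites$id) else snpB
  xA <- g$dosage[, jA]
  xB <- g$dosage[, jB]
  y <- phenotype_vector(phenotypes, trait, timepoint, individuals = ids)
  ok <- !is.na(y) & !is.na(xA) & !is.na(xB)
  xA <- xA[ok]; xB <- xB[ok]; y <- y[ok]
  if (length(unique(xA)) < 2) stop("snpA is monomorphic")
  if (length(unique(xB)) < 2) stop("snpB is monomorphic")
  if (!is.null(Q)) {
    X <- structure_covariates(Q, ids[ok])
    if (ncol(X)) y <- stats::lm.fit(cbind(1, X), y)$residuals + mean(y)
  }
  rec <- partition_cells(xA, xB, y, weighting, min_classes, min_per_class)
  rec$snpA <- g$sites$id[jA]
  rec$snpB <- g$sites$id[jB]
  rec$trait <- trait
  rec$timepoint <- timepoint
  structure(rec, class = "epistasis_record")
}

# core computation on sufficient statistics of the 3x3 table
partition_cells <- function(xA, xB, y, weighting = "observed",
                            min_classes = 5L, min_per_class = 2L) {
  ok <- !is.na(xA) & !is.na(xB) & !is.na(y)
  xA <- xA[ok]; xB <- xB[ok]; y <- y[ok]
  cell <- 3L * xA + xB + 1L                     # 1..9, A-major
  n_jk <- tabulate(cell, 9L)
  s_jk <- vapply(1:9, function(k) sum(y[cell == k]), numeric(1))
  q_jk <- vapply(1:9, function(k) sum(y[cell == k]^2), numeric(1))
  pop <- n_jk > 0
  if (sum(n_jk >= min_per_class) < min_classes)
    stop("fewer than ", min_classes, " genotype classes with >= ",
         min_per_class, " individuals; pair skipped")
  N <- sum(n_jk)
  m_jk <- ifelse(pop, s_jk / pmax(n_jk, 1), NA_real_)
  ss_total <- sum(q_jk) - sum(s_jk)^2 / N
  rss_full <- sum(q_jk) - sum(s_jk[pop]^2 / n_jk[pop])
  # additive (A factor + B factor) model, weighted LS on cell means
  aix <- (seq_len(9) - 1L) %/% 3L               # 0,1,2 for locus A
  bix <- (seq_len(9) - 1L) %% 3L
  kA <- sort(unique(aix[pop])); kB <- sort(unique(bix[pop]))
  Z <- cbind(1,
             stats::model.matrix(~factor(aix, levels = kA))[, -1, drop = FALSE],
             stats::model.matrix(~factor(bix, levels = kB))[, -1, drop = FALSE])
  Zp <- Z[pop, , drop = FALSE]
  wls <- stats::lm.wfit(Zp, m_jk[pop], w = n_jk[pop])
  rss_add <- rss_full + sum(n_jk[pop] * wls$residuals^2)
  df_full <- sum(pop) - 1L
  df_add <- wls$rank - 1L
  df_int <- df_full - df_add
  ss_int <- rss_add - rss_full
  df_err <- N - sum(pop)
  mse <- rss_full / df_err
  p_int <- if (df_int > 0 && df_err > 0 && mse > 0)
    stats::pf((ss_int / df_int) / mse, df_int, df_err, lower.tail = FALSE)
  else NA_real_
  # orthogonal component contrasts
  fA <- if (weighting == "observed")
    vapply(0:2, function(v) mean(xA == v), numeric(1)) else rep(1 / 3, 3)
  fB <- if (weighting == "observed")
    vapply(0:2, function(v) mean(xB == v), numeric(1)) else rep(1 / 3, 3)
  cA <- locus_contrasts(fA)
  cB <- locus_contrasts(fB)
  comps <- c("axa", "axd", "dxa", "dxd")
  comp_df <- data.frame(component = comps, ss = NA_real_, f = NA_real_,
                        p = NA_real_, estimable = FALSE,
                        stringsAsFactors = FALSE)
  for (ci in seq_along(comps)) {
    wA <- if (substr(comps[ci], 1, 1) == "a") cA$a else cA$d
    wB <- if (substr(comps[ci], 3, 3) == "a") cB$a else cB$d
    cvec <- as.vector(t(outer(wA, wB)))         # matches cell = 3*xA + xB + 1
    if (any(abs(cvec) > 1e-12 & !pop)) next     # needed class empty
    L <- sum(cvec[pop] * m_jk[pop])
    den <- sum(cvec[pop]^2 / n_jk[pop])
    if (den <= 0) next
    ssc <- L^2 / den
    comp_df$ss[ci] <- ssc
    comp_df$estimable[ci] <- TRUE
    if (mse > 0 && df_err > 0) {
      comp_df$f[ci] <- ssc / mse
      comp_df$p[ci] <- stats::pf(comp_df$f[ci], 1, df_err,
                                 lower.tail = FALSE)
    }
  }
  list(counts = matrix(n_jk, 3, 3, byrow = TRUE,
                       dimnames = list(paste0("A", 0:2), paste0("B", 0:2))),
       means = matrix(m_jk, 3, 3, byrow = TRUE,
                      dimnames = list(paste0("A", 0:2), paste0("B", 0:2))),
       ss_int = ss_int, df_int = df_int, p_int = p_int,
       components = comp_df,
       c = if (ss_total > 0) ss_int / ss_total else NA_real_,
       ss_total = ss_total, n = N, weighting = weighting)
}

#' @export
print.epistasis_record <- function(x, ...) {
  cat(sprintf("epistasis %s x %s (%s:%s): SS_int=%.3f (df %d), P=%.3g, c=%.4f\n",
              x$snpA, x$snpB, x$trait, x$timepoint, x$ss_int, x$df_int,
              x$p_int, x$c))
  invisible(x)
}

#' Two-locus epistasis scan over candidate SNP pairs
#'
#' Tests every unordered pair of the candidate SNPs (default: all filtered
#' sites; restrict to MLM-significant SNPs for the focused analysis) and
#' retains records with interaction P below `alpha`.
#'
#' @param g a `genotype_matrix`.
#' @param phenotypes long phenotype data.frame.
#' @param trait,timepoint the phenotype set.
#' @param candidates site ids or indices (default all).
#' @param alpha retention threshold on the interaction P (default 0.001).
#' @param Q optional structure covariates.
#' @param snp_features optional data.frame (`id`, `feature`) to annotate
#'   pair members for network export.
#' @return data.frame of retained pairs: `snpA`, `snpB`, `p_int`, `ss_int`,
#'   `c`, strongest `component`, feature columns when provided; attributes
#'   `n_tested` and `n_skipped`.
#' @export
epistasis_scan <- function(g, phenotypes, trait, timepoint,
                           candidates = NULL, alpha = 0.001, Q = NULL,
                           snp_features = NULL) {
  ix <- if (is.null(candidates)) seq_len(ncol(g$dosage))
  else if (is.character(candidates)) match(candidates, g$sites$id)
  else candidates
  ids <- rownames(g$dosage)
  out <- list()
  n_tested <- 0L
  n_skipped <- 0L
  m <- length(ix)
  if (m >= 2) {
    y <- phenotype_vector(phenotypes, trait, timepoint, individuals = ids)
    if (!is.null(Q)) {
      X <- structure_covariates(Q, ids)
      okq <- !is.na(y)
      if (ncol(X))
        y[okq] <- stats::lm.fit(cbind(1, X[okq, , drop = FALSE]),
                                y[okq])$residuals + mean(y[okq])
    }
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      xA <- g$dosage[, ix[i]]
      xB <- g$dosage[, ix[j]]
      ok <- !is.na(y) & !is.na(xA) & !is.na(xB)
      rec <- tryCatch(
        partition_cells(xA[ok], xB[ok], y[ok]),
        error = function(e) NULL)
      if (is.null(rec) || is.na(rec$p_int)) { n_skipped <- n_skipped + 1L; next }
      n_tested <- n_tested + 1L
      if (rec$p_int < alpha) {
        best <- if (all(is.na(rec$components$ss))) NA_character_
        else rec$components$component[which.max(rec$components$ss)]
        out[[length(out) + 1]] <- data.frame(
          snpA = g$sites$id[ix[i]], snpB = g$sites$id[ix[j]],
          p_int = rec$p_int, ss_int = rec$ss_int, c = rec$c,
          component = best, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snpA = character(0), snpB = character(0), p_int = numeric(0),
               ss_int = numeric(0), c = numeric(0), component = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(snp_features) && nrow(res)) {
    fmap <- function(id) {
      f <- snp_features$feature[snp_features$id == id]
      if (length(f)) paste(unique(f), collapse = ",") else "intergenic"
    }
    res$featureA <- vapply(res$snpA, fmap, character(1))
    res$featureB <- vapply(res$snpB, fmap, character(1))
  }
  res <- res[order(res$p_int), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "n_skipped") <- n_skipped
  res
}
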