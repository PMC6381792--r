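# Mixed-linear-model association of panel SNPs against trait x timepoint
# phenotype sets, with additive/dominance decomposition, modified-Bonferroni
# thresholds, lead-SNP clustering, PVE-trajectory classification, and
# association-hotspot detection.
#
# Variance components are estimated once per phenotype set on the no-SNP
# model via restricted likelihood on the spectral decomposition of the
# kinship matrix (the population-parameters-previously-determined
# approximation); each SNP is then tested by generalized least squares with
# those components fixed.

#' Modified-Bonferroni association thresholds
#'
#' Suggestive threshold `1/n`, significant threshold `0.05/n`, with `n` the
#' number of markers tested.
#'
#' @param n_markers number of markers.
#' @return object of class `assoc_thresholds` with elements `n_markers`,
#'   `suggestive`, `significant`.
#' @export
compute_thresholds <- function(n_markers) {
  stopifnot(n_markers >= 1)
  structure(list(n_markers = n_markers, suggestive = 1 / n_markers,
                 significant = 0.05 / n_markers),
            class = "assoc_thresholds")
}

#' @export
print.assoc_thresholds <- function(x, ...) {
  cat(sprintf("n = %d markers: suggestive P = %.3g (1/n), significant P = %.3g (0.05/n)\n",
              x$n_markers, x$suggestive, x$significant))
  invisible(x)
}

# IBS kinship from a complete (or mean-imputable) dosage matrix
ibs_kinship <- function(dosage) {
  M <- !is.na(dosage)
  A0 <- (dosage == 0) & M; A1 <- (dosage == 1) & M; A2 <- (dosage == 2) & M
  mode(A0) <- mode(A1) <- mode(A2) <- "numeric"
  mode(M) <- "numeric"
  shared <- tcrossprod(M)
  full <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  half <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  K <- (full + 0.5 * half) / pmax(shared, 1)
  K[shared == 0] <- NA_real_
  dimnames(K) <- list(rownames(dosage), rownames(dosage))
  K
}

#' Identity-by-state kinship matrix
#'
#' Pairwise IBS proportion over sites where both individuals are called;
#' diagonal 1. Individuals with all calls missing are excluded with a
#' message.
#'
#' @param g a `genotype_matrix`.
#' @return object of class `kinship_matrix` (numeric matrix with `method`
#'   attribute "IBS").
#' @export
estimate_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$dosage) < 100)
    warning("fewer than 100 SNPs; kinship estimates will be noisy")
  allmiss <- rowSums(!is.na(g$dosage)) == 0
  d <- g$dosage
  if (any(allmiss)) {
    message(sum(allmiss), " individual(s) with all calls missing excluded ",
            "from kinship")
    d <- d[!allmiss, , drop = FALSE]
  }
  K <- ibs_kinship(d)
  attr(K, "method") <- "IBS"
  class(K) <- c("kinship_matrix", class(K))
  K
}

# eigenvalue flooring so the kinship is usable as a covariance
bend_psd <- function(K, floor = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  bent <- any(e$values < floor)
  e$values <- pmax(e$values, floor)
  list(U = e$vectors, d = e$values, bent = bent)
}

# REML profile over lambda = sigma_g^2 / sigma_e^2 on the rotated model
reml_lambda <- function(yt, Xt, d) {
  n <- length(yt)
  p <- ncol(Xt)
  ldXX <- determinant(crossprod(Xt), logarithm = TRUE)$modulus
  nll <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    XtW <- Xt / w
    XX <- crossprod(Xt, XtW)
    b <- solve(XX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(r^2 / w)
    s2 <- rss / (n - p)
    0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
             determinant(XX, logarithm = TRUE)$modulus - ldXX)
  }
  opt <- stats::optimize(nll, c(-10, 10))
  exp(opt$minimum)
}

#' Mixed-linear-model association scan for one phenotype set
#'
#' The model is y = Q beta + x b + u + e with u ~ N(0, sigma_g^2 K). The
#' variance ratio is fit once on the no-SNP model (restricted likelihood via
#' the spectral decomposition of K), then every SNP is tested by generalized
#' least squares with a Wald chi-square test of the dosage term. Missing
#' dosages are mean-imputed per SNP (association only; population-genetic
#' statistics never impute).
#'
#' @param g a `genotype_matrix`.
#' @param phenotypes long phenotype data.frame (`individual`, `trait`,
#'   `timepoint`, `value`).
#' @param trait,timepoint the phenotype set.
#' @param K kinship matrix (default [estimate_kinship()]).
#' @param Q structure covariates: subpopulation labels (factor/character),
#'   a numeric matrix (e.g. principal components), or NULL. Default: the
#'   genotype matrix's subpop labels.
#' @param per_snp_reml refit the variance components for every SNP (slow;
#'   default FALSE uses the one-fit approximation).
#' @return data.frame, one row per SNP: `id`, `chrom`, `pos`, `beta`, `se`,
#'   `p`, `pve`, `maf`, `n`, plus attributes `lambda_gc` (genomic inflation)
#'   and `vc_lambda` (fitted variance ratio).
#' @export
mlm_scan <- function(g, phenotypes, trait, timepoint, K = NULL, Q = g$subpop,
                     per_snp_reml = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$dosage)
  y <- phenotype_vector(phenotypes, trait, timepoint, individuals = ids)
  ok <- !is.na(y)
  if (sum(ok) < 50)
    stop("phenotype present for fewer than 50 individuals")
  if (is.null(K)) K <- estimate_kinship(g)
  Km <- unclass(K)[ids, ids][ok, ok]
  X <- structure_covariates(Q, ids)[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  eg <- bend_psd(Km)
  U <- eg$U; dvals <- eg$d
  yt <- crossprod(U, y)
  Xt <- crossprod(U, cbind(`(Intercept)` = 1, X))
  lam <- reml_lambda(yt, Xt, dvals)
  w <- lam * dvals + 1
  D <- g$dosage[ok, , drop = FALSE]
  cmn <- colMeans(D, na.rm = TRUE)
  naix <- which(is.na(D), arr.ind = TRUE)
  if (nrow(naix)) D[naix] <- cmn[naix[, 2]]
  Dt <- crossprod(U, D)
  p0 <- ncol(Xt)
  # null weighted RSS for PVE
  XtW0 <- Xt / w
  b0 <- solve(crossprod(Xt, XtW0), crossprod(XtW0, yt))
  rss0 <- sum((yt - Xt %*% b0)^2 / w)
  m <- ncol(D)
  beta <- se <- pval <- pve <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    xj <- Dt[, j]
    if (stats::sd(D[, j]) < 1e-10) next
    if (per_snp_reml) {
      lam_j <- reml_lambda(yt, cbind(Xt, xj), dvals)
      wj <- lam_j * dvals + 1
    } else wj <- w
    Xj <- cbind(Xt, snp = xj)
    XjW <- Xj / wj
    XX <- crossprod(Xj, XjW)
    bj <- tryCatch(solve(XX, crossprod(XjW, yt)), error = function(e) NULL)
    if (is.null(bj)) next
    r <- yt - Xj %*% bj
    rss1 <- sum(r^2 / wj)
    s2 <- rss1 / (n - p0 - 1)
    vb <- s2 * solve(XX)[p0 + 1, p0 + 1]
    beta[j] <- bj[p0 + 1]
    se[j] <- sqrt(vb)
    pval[j] <- stats::pchisq(beta[j]^2 / vb, df = 1, lower.tail = FALSE)
    pve[j] <- 1 - rss1 / rss0
  }
  out <- data.frame(id = g$sites$id, chrom = g$sites$chrom,
                    pos = g$sites$pos, beta = beta, se = se, p = pval,
                    pve = pve, maf = site_maf(g), n = n,
                    trait = trait, timepoint = timepoint,
                    stringsAsFactors = FALSE)
  chi <- stats::qchisq(out$p, df = 1, lower.tail = FALSE)
  attr(out, "lambda_gc") <- stats::median(chi, na.rm = TRUE) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  attr(out, "vc_lambda") <- lam
  attr(out, "bent") <- eg$bent
  out
}

structure_covariates <- function(Q, ids) {
  if (is.null(Q)) return(matrix(numeric(0), length(ids), 0))
  if (is.matrix(Q)) return(Q[ids, , drop = FALSE])
  q <- if (!is.null(names(Q))) Q[ids] else Q
  f <- factor(q)
  if (nlevels(f) < 2) return(matrix(numeric(0), length(ids), 0))
  X <- stats::model.matrix(~f)[, -1, drop = FALSE]
  rownames(X) <- ids
  X
}

#' Additive/dominance effect classification for one SNP
#'
#' Least-squares means of the three genotype classes under a Q-adjusted
#' linear model. The additive contrast compares the two homozygote classes
#' (a = (mean(AA) - mean(aa)) / 2); the dominance contrast compares the
#' heterozygote mean with the homozygote midpoint
#' (d = mean(Aa) - (mean(AA) + mean(aa)) / 2). Class is `both`, `additive`,
#' `dominant` or `none` at significance `alpha`. When any genotype class has
#' fewer than `min_class` individuals the dominance contrast is not
#' estimable and the record is restricted to the additive (dosage) test,
#' flagged `restricted`.
#'
#' @param g a `genotype_matrix`.
#' @param phenotypes long phenotype data.frame.
#' @param trait,timepoint the phenotype set.
#' @param snp site id or column index.
#' @param Q structure covariates as in [mlm_scan()].
#' @param alpha contrast significance level (default 0.001).
#' @param min_class minimum individuals per genotype class (default 3).
#' @return list: `class`, `a`, `d`, their standard errors `se_a`, `se_d`,
#'   `p_additive`, `p_dominance`, `ls_means`, `restricted`.
#' @export
classify_effect <- function(g, phenotypes, trait, timepoint, snp,
                            Q = g$subpop, alpha = 0.001, min_class = 3L) {
  ids <- rownames(g$dosage)
  j <- if (is.character(snp)) match(snp, g$sites$id) else snp
  x <- g$dosage[, j]
  y <- phenotype_vector(phenotypes, trait, timepoint, individuals = ids)
  ok <- !is.na(y) & !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) stop("SNP ", snp, " is monomorphic")
  X <- structure_covariates(Q, ids)[ok, , drop = FALSE]
  if (ncol(X)) X <- scale(X, scale = FALSE)     # center: LS means at mean Q
  counts <- tabulate(x + 1L, nbins = 3L)
  if (any(counts < min_class)) {
    # dosage (additive) test only
    fit <- stats::lm(y ~ X + x)
    ct <- stats::coef(summary(fit))
    pa <- ct[nrow(ct), 4]
    return(list(class = if (pa < alpha) "additive" else "none",
                a = unname(stats::coef(fit)[length(stats::coef(fit))]),
                d = NA_real_, se_a = unname(ct[nrow(ct), 2]),
                se_d = NA_real_, p_additive = pa, p_dominance = NA_real_,
                ls_means = NULL, restricted = TRUE))
  }
  I1 <- as.numeric(x == 1)
  I2 <- as.numeric(x == 2)
  Xf <- cbind(`(Intercept)` = 1, X, het = I1, hom2 = I2)
  fit <- stats::lm.fit(Xf, y)
  nc <- ncol(Xf)
  cf <- fit$coefficients
  s2 <- sum(fit$residuals^2) / (length(y) - fit$rank)
  R <- qr.R(fit$qr)
  covb_p <- chol2inv(R) * s2
  covb <- matrix(NA_real_, nc, nc)
  piv <- fit$qr$pivot[seq_len(fit$rank)]
  covb[piv, piv] <- covb_p
  mu <- cf["(Intercept)"]
  m0 <- mu; m1 <- mu + cf["het"]; m2 <- mu + cf["hom2"]
  a <- unname((m2 - m0) / 2)
  d <- unname(cf["het"] - cf["hom2"] / 2)
  ia <- which(colnames(Xf) == "hom2")
  id_ <- which(colnames(Xf) == "het")
  # additive contrast: hom2 coefficient; dominance: het - hom2/2
  va <- covb[ia, ia]
  cd <- rep(0, nc); cd[id_] <- 1; cd[ia] <- -0.5
  vd <- drop(t(cd) %*% covb %*% cd)
  dfres <- length(y) - fit$rank
  pa <- 2 * stats::pt(abs(cf["hom2"] / sqrt(va)), dfres, lower.tail = FALSE)
  pd <- 2 * stats::pt(abs(d / sqrt(vd)), dfres, lower.tail = FALSE)
  cls <- if (pa < alpha && pd < alpha) "both"
  else if (pa < alpha) "additive"
  else if (pd < alpha) "dominant"
  else "none"
  list(class = cls, a = a, d = d,
       se_a = sqrt(va) / 2, se_d = sqrt(vd),
       p_additive = unname(pa), p_dominance = unname(pd),
       ls_means = c(aa = unname(m0), Aa = unname(m1), AA = unname(m2)),
       restricted = FALSE)
}

#' Classify a PVE trajectory over timepoints
#'
#' Rule-based: least-squares slopes of PVE against timepoint index overall
#' and within the first and second halves. `increasing`: both half-slopes
#' above `tol`; `decreasing`: both below `-tol`; `level`: both within
#' `+/-tol`; `increase-then-level`: first above `tol`, second within
#' `+/-tol`; anything else (or fewer than 4 timepoints) is `unclassified`.
#'
#' @param pve numeric PVE values in timepoint order.
#' @param time numeric time axis (default: index).
#' @param tol slope tolerance in PVE units per timepoint step (default
#'   0.005).
#' @return the pattern label.
#' @export
classify_trajectory <- function(pve, time = seq_along(pve), tol = 0.005) {
  ok <- !is.na(pve)
  pve <- pve[ok]; time <- time[ok]
  if (length(pve) < 4) return("unclassified")
  sl <- function(ix) unname(stats::coef(stats::lm(pve[ix] ~ time[ix]))[2])
  half <- ceiling(length(pve) / 2)
  s1 <- sl(seq_len(half))
  s2 <- sl(seq(half, length(pve)))
  if (s1 > tol && s2 > tol) "increasing"
  else if (s1 < -tol && s2 < -tol) "decreasing"
  else if (abs(s1) <= tol && abs(s2) <= tol) "level"
  else if (s1 > tol && abs(s2) <= tol) "increase-then-level"
  else "unclassified"
}

#' Association hotspot features across phenotype sets
#'
#' For each feature (gene or ncRNA), counts the number of distinct phenotype
#' sets with at least one associated SNP below `threshold`. The null is
#' built by shuffling phenotype-set labels over the association events
#' `n_perm` times and taking the `(1 - alpha)` quantile of the per-permutation
#' maximum feature count. Features reaching both `k_min` sets and the
#' permutation threshold are flagged.
#'
#' @param records association records across sets (needs `id`, `trait`,
#'   `timepoint`, `p`).
#' @param snp_features data.frame mapping SNP `id` to `feature` (one row per
#'   SNP-feature link; SNPs without features are ignored).
#' @param threshold association P-value cut-off defining an event.
#' @param k_min minimum phenotype-set count (12 at the suggestive threshold,
#'   8 at the significant threshold).
#' @param n_perm permutations (default 1000).
#' @param alpha permutation significance level (default 0.05).
#' @param seed RNG seed.
#' @return data.frame per feature: `feature`, `n_sets`, `hotspot`; attribute
#'   `perm_cut`.
#' @export
find_hotspot_features <- function(records, snp_features, threshold,
                                  k_min = 12L, n_perm = 1000, alpha = 0.05,
                                  seed = 1L) {
  set.seed(seed)
  ev <- records[!is.na(records$p) & records$p <= threshold, , drop = FALSE]
  if (nrow(ev) == 0)
    return(structure(data.frame(feature = character(0), n_sets = integer(0),
                                hotspot = logical(0)), perm_cut = Inf))
  ev <- merge(ev, snp_features, by = "id")
  if (nrow(ev) == 0)
    return(structure(data.frame(feature = character(0), n_sets = integer(0),
                                hotspot = logical(0)), perm_cut = Inf))
  ev$set <- paste0(ev$trait, ":", ev$timepoint)
  count_sets <- function(sets, feats)
    vapply(split(sets, feats), function(s) length(unique(s)), integer(1))
  obs <- count_sets(ev$set, ev$feature)
  null_max <- vapply(seq_len(n_perm), function(b)
    max(count_sets(sample(ev$set), ev$feature)), integer(1))
  cut <- stats::quantile(null_max, 1 - alpha, names = FALSE)
  out <- data.frame(feature = names(obs), n_sets = as.integer(obs),
                    stringsAsFactors = FALSE)
  out$hotspot <- out$n_sets >= k_min & out$n_sets > cut
  out <- out[order(-out$n_sets), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, perm_cut = cut)
}

#' Greedy lead-SNP clustering of association signals
#'
#' Within one phenotype set, the lowest-P significant SNP becomes a lead;
#' every significant SNP with `r2 >= r2_cut` to that lead joins its signal;
#' the procedure repeats on the remainder. Ties in P resolve to the smaller
#' genomic coordinate. Optionally reports features within `feature_window`
#' bp of each lead.
#'
#' @param records association records of one phenotype set (`id`, `chrom`,
#'   `pos`, `p`).
#' @param g the `genotype_matrix` (used to compute pairwise r-squared to the
#'   lead).
#' @param threshold significance cut-off for inclusion.
#' @param r2_cut LD cut-off separating signals (default 0.2).
#' @param features optional data.frame (`feature`, `chrom`, `start`, `end`)
#'   of candidate features.
#' @param feature_window candidate window around the lead (default 10 kb).
#' @return data.frame, one row per unique signal: `lead`, `chrom`, `pos`,
#'   `p`, `n_members`, `members`, `candidates`.
#' @export
lead_snp_clusters <- function(records, g, threshold, r2_cut = 0.2,
                              features = NULL, feature_window = 10000L) {
  sig <- records[!is.na(records$p) & records$p <= threshold, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(lead = character(0), chrom = character(0),
                      pos = integer(0), p = numeric(0),
                      n_members = integer(0), members = character(0),
                      candidates = character(0), stringsAsFactors = FALSE))
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  out <- NULL
  remaining <- sig
  while (nrow(remaining)) {
    lead <- remaining[1, ]
    jl <- match(lead$id, g$sites$id)
    r2 <- vapply(remaining$id, function(idb) {
      jb <- match(idb, g$sites$id)
      ok <- !is.na(g$dosage[, jl]) & !is.na(g$dosage[, jb])
      if (sum(ok) < 2) return(0)
      a <- g$dosage[ok, jl]; b <- g$dosage[ok, jb]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)^2
    }, numeric(1))
    member <- r2 >= r2_cut
    member[1] <- TRUE
    cand <- ""
    if (!is.null(features)) {
      fx <- features[features$chrom == lead$chrom &
                       features$end >= lead$pos - 1L - feature_window &
                       features$start <= lead$pos - 1L + feature_window, ]
      cand <- paste(fx$feature, collapse = ",")
    }
    out <- rbind(out, data.frame(
      lead = lead$id, chrom = lead$chrom, pos = lead$pos, p = lead$p,
      n_members = sum(member),
      members = paste(remaining$id[member], collapse = ","),
      candidates = cand, stringsAsFactors = FALSE))
    remaining <- remaining[!member, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
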