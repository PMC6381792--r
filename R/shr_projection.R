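# Projection of QTL support intervals (genetic map, cM) onto genomic
# coordinates (bp) through anchor markers with known positions in both
# systems, yielding segmental homology regions (SHRs).

#' Fit a piecewise-linear cM-to-bp map from anchor markers
#'
#' Monotone piecewise-linear interpolation between consecutive anchors of one
#' linkage group. Requires at least `min_anchors` anchors; anchors whose bp
#' order contradicts their cM order (local inversion/rearrangement) make the
#' LG unprojectable and are flagged rather than resolved.
#'
#' @param anchors anchor table data.frame: `marker`, `lg`, `cm`, `chrom`,
#'   `bp`.
#' @param lg linkage group to fit.
#' @param min_anchors minimum anchor count (default 3).
#' @return object of class `anchor_map` (`lg`, `chrom`, `cm`, `bp`,
#'   `orientation`), or an error for unprojectable LGs.
#' @export
fit_anchor_map <- function(anchors, lg, min_anchors = 3L) {
  a <- anchors[anchors$lg == lg, , drop = FALSE]
  if (nrow(a) < min_anchors)
    stop("LG ", lg, " has ", nrow(a), " anchors; need >= ", min_anchors)
  if (length(unique(a$chrom)) > 1)
    stop("LG ", lg, " anchors map to multiple chromosomes: ",
         paste(unique(a$chrom), collapse = ", "))
  a <- a[order(a$cm), ]
  if (anyDuplicated(a$cm)) a <- a[!duplicated(a$cm), ]
  inc <- all(diff(a$bp) > 0)
  dec <- all(diff(a$bp) < 0)
  if (!inc && !dec)
    stop("LG ", lg, " anchors are not co-monotone in cM and bp ",
         "(local inversion/rearrangement); region not projected")
  structure(list(lg = lg, chrom = a$chrom[1], cm = a$cm, bp = a$bp,
                 orientation = if (inc) 1 else -1),
            class = "anchor_map")
}

#' Convert map positions (cM) to genomic coordinates (bp)
#'
#' Linear interpolation within the anchored range; queries beyond the
#' terminal anchors are extrapolated with the nearest segment's slope and
#' flagged in the `extrapolated` attribute.
#'
#' @param am an `anchor_map` from [fit_anchor_map()].
#' @param cm query positions in cM.
#' @return numeric bp positions, with logical attribute `extrapolated`.
#' @export
cm_to_bp <- function(am, cm) {
  stopifnot(inherits(am, "anchor_map"))
  bp <- stats::approx(am$cm, am$bp, xout = cm, rule = 1)$y
  lo <- cm < min(am$cm)
  hi <- cm > max(am$cm)
  k <- length(am$cm)
  if (any(lo)) {
    s <- (am$bp[2] - am$bp[1]) / (am$cm[2] - am$cm[1])
    bp[lo] <- am$bp[1] + s * (cm[lo] - am$cm[1])
  }
  if (any(hi)) {
    s <- (am$bp[k] - am$bp[k - 1]) / (am$cm[k] - am$cm[k - 1])
    bp[hi] <- am$bp[k] + s * (cm[hi] - am$cm[k])
  }
  attr(bp, "extrapolated") <- lo | hi
  bp
}

#' Convert genomic coordinates (bp) back to map positions (cM)
#'
#' Inverse of [cm_to_bp()] within the anchored range.
#'
#' @param am an `anchor_map`.
#' @param bp query positions in bp.
#' @return numeric cM positions.
#' @export
bp_to_cm <- function(am, bp) {
  stopifnot(inherits(am, "anchor_map"))
  o <- order(am$bp)
  stats::approx(am$bp[o], am$cm[o], xout = bp, rule = 2)$y
}

#' Project QTL overlap regions onto the genome as SHRs
#'
#' Each region's cM interval is mapped through its LG's anchor map; regions
#' whose projected genomic intervals overlap (>= 1 bp) are merged into a
#' single SHR. Regions on LGs without a valid anchor map are reported in the
#' `failed` component and the projection continues.
#'
#' @param regions overlap-region data.frame from [cluster_colocalized()]
#'   (`region`, `lg`, `cm_lo`, `cm_hi`, `n_qtl`).
#' @param anchors anchor table (`marker`, `lg`, `cm`, `chrom`, `bp`).
#' @param min_anchors minimum anchors per LG (default 3).
#' @return list with `shr` (data.frame: `name`, `chrom`, `start`, `end`,
#'   `n_regions`, `n_qtl`, `cm_per_mb`, `source_regions`), `projected`
#'   (per-region projections), and `failed` (region id + reason).
#' @export
project_regions <- function(regions, anchors, min_anchors = 3L) {
  proj <- NULL
  failed <- NULL
  for (i in seq_len(nrow(regions))) {
    am <- tryCatch(fit_anchor_map(anchors, regions$lg[i], min_anchors),
                   error = function(e) conditionMessage(e))
    if (is.character(am)) {
      failed <- rbind(failed, data.frame(region = regions$region[i],
                                         reason = am,
                                         stringsAsFactors = FALSE))
      next
    }
    bp <- cm_to_bp(am, c(regions$cm_lo[i], regions$cm_hi[i]))
    lohi <- sort(bp)
    span_cm <- regions$cm_hi[i] - regions$cm_lo[i]
    proj <- rbind(proj, data.frame(
      region = regions$region[i], lg = regions$lg[i], chrom = am$chrom,
      start = max(0, floor(lohi[1])), end = ceiling(lohi[2]),
      n_qtl = regions$n_qtl[i],
      cm_per_mb = if (lohi[2] > lohi[1])
        span_cm / ((lohi[2] - lohi[1]) / 1e6) else NA_real_,
      extrapolated = any(attr(bp, "extrapolated")),
      stringsAsFactors = FALSE))
  }
  if (is.null(proj))
    return(list(shr = data.frame(name = character(0), chrom = character(0),
                                 start = integer(0), end = integer(0),
                                 n_regions = integer(0), n_qtl = integer(0),
                                 cm_per_mb = numeric(0),
                                 source_regions = character(0),
                                 stringsAsFactors = FALSE),
                projected = proj, failed = failed))
  proj$end <- pmax(proj$end, proj$start + 1)      # degenerate points widen
  proj <- proj[order(proj$chrom, proj$start), , drop = FALSE]
  newgrp <- c(TRUE, proj$chrom[-1] != proj$chrom[-nrow(proj)] |
                proj$start[-1] >= cummax_by_group(proj))
  grp <- cumsum(newgrp)
  shr <- do.call(rbind, lapply(split(seq_len(nrow(proj)), grp), function(ix) {
    data.frame(chrom = proj$chrom[ix[1]], start = min(proj$start[ix]),
               end = max(proj$end[ix]), n_regions = length(ix),
               n_qtl = sum(proj$n_qtl[ix]),
               cm_per_mb = mean(proj$cm_per_mb[ix], na.rm = TRUE),
               source_regions = paste(proj$region[ix], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  shr <- cbind(name = sprintf("SHR%02d", seq_len(nrow(shr))), shr,
               stringsAsFactors = FALSE)
  rownames(shr) <- NULL
  list(shr = shr, projected = proj, failed = failed)
}

# running maximum of interval ends within the current chromosome, shifted by
# one, for overlap-chain detection on sorted intervals
cummax_by_group <- function(proj) {
  ends <- numeric(nrow(proj))
  cur <- -Inf
  chrom <- ""
  for (i in seq_len(nrow(proj))) {
    if (proj$chrom[i] != chrom) { cur <- -Inf; chrom <- proj$chrom[i] }
    ends[i] <- cur
    cur <- max(cur, proj$end[i])
  }
  ends[-1]
}
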