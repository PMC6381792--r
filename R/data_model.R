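# ---- FilterConfig ----------------------------------------------------------

#' Site filter configuration
#'
#' Thresholds applied to panel SNP sites after VCF import: sites with a
#' missing-call fraction above `max_missing` or a minor allele frequency
#' (computed from non-missing calls only) below `min_maf` are removed.
#' `flank_bp` is the gene flank used by the annotation module to call a SNP
#' genic rather than intergenic.
#'
#' @param max_missing maximum tolerated fraction of missing genotype calls
#'   per site (default 0.10).
#' @param min_maf minimum minor allele frequency per site (default 0.05).
#' @param flank_bp gene flank width in bp for genic annotation (default 2000).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(max_missing = 0.10, min_maf = 0.05, flank_bp = 2000L) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1,
            flank_bp >= 0)
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 flank_bp = as.integer(flank_bp)),
            class = "filter_config")
}

# ---- GenotypeMatrix --------------------------------------------------------

#' Construct a genotype matrix
#'
#' Container for a diploid panel: individuals x biallelic sites, dosage-coded
#' as the count of the alternate allele (0/1/2, `NA` = missing), with per-site
#' metadata and an optional subpopulation assignment.
#'
#' @param dosage integer matrix, individuals in rows, sites in columns;
#'   entries in `{0, 1, 2, NA}`. Row names are individual ids.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per column of `dosage`.
#' @param subpop optional character vector (named by individual, or in row
#'   order) assigning each individual to a subpopulation label.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, subpop = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(sites))
    stop("sites must have one row per dosage column")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    stop("dosages must be in {0, 1, 2} or NA")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites needs columns: ", paste(need, collapse = ", "))
  if (is.null(sites$id))
    sites$id <- paste0(sites$chrom, "_", sites$pos)
  colnames(dosage) <- sites$id
  if (!is.null(subpop)) {
    if (!is.null(names(subpop))) {
      subpop <- subpop[rownames(dosage)]
      if (anyNA(subpop))
        stop("subpop labels missing for individual(s): ",
             paste(utils::head(rownames(dosage)[is.na(subpop)], 5),
                   collapse = ", "))
    }
    if (length(subpop) != nrow(dosage))
      stop("subpop must cover every individual")
    subpop <- stats::setNames(as.character(subpop), rownames(dosage))
  }
  structure(list(dosage = dosage, sites = sites, subpop = subpop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites\n",
              nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$subpop)) {
    tb <- table(x$subpop)
    cat("subpopulations:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-site minor allele frequency
#'
#' MAF from non-missing calls only; `NA` for all-missing sites.
#'
#' @param g a `genotype_matrix`, or a dosage matrix.
#' @param individuals optional subset of individuals (ids or indices).
#' @return numeric vector, one MAF per site.
#' @export
site_maf <- function(g, individuals = NULL) {
  d <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  n <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n)
  p[n == 0] <- NA_real_
  pmin(p, 1 - p)
}

#' Per-site missing-call fraction
#' @inheritParams site_maf
#' @return numeric vector of missing fractions.
#' @export
site_missing <- function(g) {
  d <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  colMeans(is.na(d))
}

#' Apply site filters to a genotype matrix
#'
#' Removes sites whose missing fraction exceeds `filter$max_missing` or whose
#' MAF (non-missing calls) is below `filter$min_maf`. Idempotent: applying the
#' same configuration twice is a no-op.
#'
#' @param g a `genotype_matrix`.
#' @param filter a [filter_config()].
#' @return filtered `genotype_matrix`; attribute `n_dropped` records counts.
#' @export
apply_filter <- function(g, filter = filter_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(filter, "filter_config"))
  miss <- site_missing(g)
  maf <- site_maf(g)
  keep <- miss <= filter$max_missing & !is.na(maf) & maf >= filter$min_maf
  out <- genotype_matrix(g$dosage[, keep, drop = FALSE],
                         g$sites[keep, , drop = FALSE], g$subpop)
  attr(out, "n_dropped") <- c(missing = sum(miss > filter$max_missing),
                              maf = sum(is.na(maf) | maf < filter$min_maf))
  out
}

# ---- VCF I/O ---------------------------------------------------------------

#' Read panel genotypes from a VCF file
#'
#' Parses a VCF (via `vcfR`), keeps biallelic SNP/indel records only
#' (multi-allelic records are skipped and counted), converts `GT` calls to
#' alternate-allele dosages, then applies the site filter.
#'
#' @param path VCF file (plain or gzipped).
#' @param filter a [filter_config()]; pass `NULL` to skip filtering.
#' @param subpop optional named character vector of subpopulation labels.
#' @return a `genotype_matrix`. Attribute `n_skipped_multiallelic` records how
#'   many records were skipped.
#' @export
read_vcf <- function(path, filter = filter_config(), subpop = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records: ", path)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT)
  n_skip <- sum(!biallelic)
  if (!any(biallelic)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  fix <- fix[biallelic, , drop = FALSE]
  if (nrow(fix) == 1) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(v@gt)[-1]))
  dos <- apply(gt, 2, gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(fix))
  dos <- t(dos)            # individuals x sites
  rownames(dos) <- colnames(gt)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                  paste0(fix$CHROM, "_", fix$POS), fix$ID),
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, sites, subpop)
  if (!is.null(filter)) {
    g <- apply_filter(g, filter)
    if (ncol(g$dosage) == 0)
      stop("no sites survive filtering (max_missing=", filter$max_missing,
           ", min_maf=", filter$min_maf, ") in ", path)
  }
  attr(g, "n_skipped_multiallelic") <- n_skip
  g
}

gt_to_dosage <- function(gt) {
  a <- sub("^([0-9.]+)[/|]([0-9.]+).*$", "\\1,\\2", gt)
  parts <- strsplit(a, ",", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2 || any(p == ".")) return(NA_integer_)
    sum(as.integer(p) > 0L)
  }, integer(1))
}

#' Write a genotype matrix as plain-text VCF
#'
#' Minimal VCF v4.2 emitter (GT only) so simulated panels round-trip through
#' [read_vcf()].
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- g$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtmap[as.character(d[ok])]
  body <- cbind(g$sites$chrom, g$sites$pos, g$sites$id, g$sites$ref,
                g$sites$alt, ".", "PASS", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- LinkageDataset --------------------------------------------------------

#' Construct a linkage dataset
#'
#' Bundles a genetic map, pseudo-testcross progeny marker calls, and a
#' longitudinal phenotype table. Marker calls are two-class (`0`/`1`, the two
#' segregating classes of the informative parent) with `NA` for missing.
#'
#' @param map data.frame with columns `lg`, `marker`, `cm`; cM positions must
#'   be strictly increasing within each linkage group.
#' @param calls matrix, progeny in rows, markers in columns, values in
#'   `{0, 1, NA}`; column names must all appear in `map$marker`.
#' @param phenotypes data.frame with columns `individual`, `trait`,
#'   `timepoint`, `value`. A (trait, timepoint) pair is one "phenotype set".
#' @return an object of class `linkage_dataset`.
#' @export
linkage_dataset <- function(map, calls, phenotypes) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("lg", "marker", "cm") %in% names(map)))
  map$cm <- as.numeric(map$cm)
  bad <- unlist(lapply(split(map, map$lg), function(m)
    if (is.unsorted(m$cm, strictly = TRUE)) unique(m$lg) else NULL))
  if (length(bad))
    stop("cM positions not strictly increasing within LG(s): ",
         paste(bad, collapse = ", "))
  calls <- as.matrix(calls)
  unknown <- setdiff(colnames(calls), map$marker)
  if (length(unknown))
    stop("progeny calls reference markers absent from the map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("progeny calls must be two-class {0,1} or NA")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("prog", seq_len(nrow(calls)))
  phenotypes <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "trait", "timepoint", "value") %in%
                  names(phenotypes)))
  if (any(is.infinite(phenotypes$value)))
    stop("phenotype values must be finite where present")
  structure(list(map = map, calls = calls, phenotypes = phenotypes),
            class = "linkage_dataset")
}

#' @export
print.linkage_dataset <- function(x, ...) {
  cat(sprintf("linkage_dataset: %d progeny, %d markers on %d LGs, %d phenotype sets\n",
              nrow(x$calls), nrow(x$map), length(unique(x$map$lg)),
              nrow(unique(x$phenotypes[c("trait", "timepoint")]))))
  invisible(x)
}

#' Read linkage-mapping inputs from TSV files
#'
#' @param map_path TSV with columns `lg`, `marker`, `cm`.
#' @param calls_path TSV, first column `progeny`, remaining columns markers.
#' @param pheno_path TSV with columns `individual`, `trait`, `timepoint`,
#'   `value`.
#' @return a validated `linkage_dataset`.
#' @export
read_linkage_inputs <- function(map_path, calls_path, pheno_path) {
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  calls_df <- utils::read.delim(calls_path, stringsAsFactors = FALSE,
                                check.names = FALSE)
  calls <- as.matrix(calls_df[, -1, drop = FALSE])
  rownames(calls) <- calls_df[[1]]
  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)
  linkage_dataset(map, calls, pheno)
}

#' Write a linkage dataset to TSV files
#'
#' Inverse of [read_linkage_inputs()].
#'
#' @param x a `linkage_dataset`.
#' @param map_path,calls_path,pheno_path output paths.
#' @return invisibly, the three paths.
#' @export
write_linkage_dataset <- function(x, map_path, calls_path, pheno_path) {
  stopifnot(inherits(x, "linkage_dataset"))
  utils::write.table(x$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  calls_df <- data.frame(progeny = rownames(x$calls), x$calls,
                         check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(calls_df, calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$phenotypes, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(map_path, calls_path, pheno_path))
}

#' Extract one phenotype set as a vector aligned to progeny/individuals
#'
#' @param x a `linkage_dataset` or a phenotype data.frame.
#' @param trait,timepoint the phenotype set.
#' @param individuals individual ids defining order (default: progeny rows).
#' @return named numeric vector (NA where unmeasured).
#' @export
phenotype_vector <- function(x, trait, timepoint, individuals = NULL) {
  ph <- if (inherits(x, "linkage_dataset")) x$phenotypes else x
  if (is.null(individuals)) {
    if (inherits(x, "linkage_dataset")) individuals <- rownames(x$calls)
    else individuals <- unique(ph$individual)
  }
  sel <- ph$trait == trait & ph$timepoint == timepoint
  y <- stats::setNames(rep(NA_real_, length(individuals)), individuals)
  hit <- ph[sel, ]
  y[match(hit$individual, individuals)] <- hit$value
  y
}

#' Enumerate phenotype sets present in a phenotype table
#'
#' @param x a `linkage_dataset` or phenotype data.frame.
#' @return data.frame with columns `trait`, `timepoint`.
#' @export
phenotype_sets <- function(x) {
  ph <- if (inherits(x, "linkage_dataset")) x$phenotypes else x
  unique(ph[, c("trait", "timepoint")])
}

# ---- Genomic intervals (BED) -----------------------------------------------

#' Validate a genomic interval table
#'
#' Intervals are 0-based half-open throughout the package; VCF positions
#' (1-based) are converted at the boundary.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @return the validated data.frame (name column filled in).
#' @export
genomic_intervals <- function(intervals) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("invalid interval(s): start must be < end (0-based half-open)")
  if (is.null(intervals$name))
    intervals$name <- if (nrow(intervals))
      paste0("iv", seq_len(nrow(intervals))) else character(0)
  intervals
}

#' Write genomic intervals to a BED file
#'
#' Output is 0-based half-open and sorted by (chrom, start).
#'
#' @param intervals data.frame accepted by [genomic_intervals()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  iv <- genomic_intervals(intervals)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  if (nrow(iv) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    name = iv$name)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`, `name` (0-based half-open).
#' @export
read_intervals <- function(path) {
  if (file.info(path)$size == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- paste0("iv", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}
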