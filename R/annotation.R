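# SNP classification relative to gene models (synonymous / nonsynonymous /
# genic-noncoding / intergenic, with an independent ncRNA overlap flag) and
# per-class diversity summaries.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# CDS segments of one gene in translation order, with cumulative offsets
cds_in_order <- function(gm, gene_id) {
  cd <- gm$cds[gm$cds$gene_id == gene_id, , drop = FALSE]
  strand <- gm$genes$strand[gm$genes$gene_id == gene_id]
  cd <- cd[order(cd$start, decreasing = (strand == "-")), , drop = FALSE]
  cd$len <- cd$end - cd$start
  cd$cum <- cumsum(c(0, utils::head(cd$len, -1)))
  attr(cd, "strand") <- strand
  cd
}

#' Annotate SNPs relative to gene models
#'
#' Codon-level synonymous/nonsynonymous determination for SNPs in CDS (using
#' the standard genetic code, strand-aware); SNPs within a gene span or
#' within `flank_bp` of one are `genic_noncoding`; everything else is
#' `intergenic`. Overlap with ncRNA records is annotated independently of the
#' primary class. A SNP hit by several overlapping genes takes the most
#' severe class (nonsynonymous > synonymous > genic_noncoding); all classes
#' are kept in `all_classes`.
#'
#' @param g a `genotype_matrix` (sites on the gene-model chromosome).
#' @param gm a `gene_model_set` with reference sequence (`seq` non-NULL when
#'   any SNP falls in CDS).
#' @param flank_bp gene flank width (default 2000, cf. [filter_config()]).
#' @return data.frame per SNP: `id`, `chrom`, `pos`, `class`, `gene_id`,
#'   `ncrna`, `all_classes`, `unannotatable`.
#' @export
annotate_snps <- function(g, gm, flank_bp = 2000L) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(gm, "gene_model_set"))
  sites <- g$sites
  n <- nrow(sites)
  sev <- c(nonsynonymous = 3, synonymous = 2, genic_noncoding = 1)
  out <- data.frame(id = sites$id, chrom = sites$chrom, pos = sites$pos,
                    class = "intergenic", gene_id = NA_character_,
                    ncrna = FALSE, all_classes = "",
                    unannotatable = FALSE, stringsAsFactors = FALSE)
  cds_cache <- lapply(stats::setNames(gm$genes$gene_id, gm$genes$gene_id),
                      function(id) cds_in_order(gm, id))
  refseq <- if (!is.null(gm$seq)) gm$seq[[1]] else NULL
  for (i in seq_len(n)) {
    if (sites$chrom[i] != gm$chrom) next
    p0 <- sites$pos[i] - 1L                     # 0-based
    out$ncrna[i] <- any(p0 >= gm$ncrna$start & p0 < gm$ncrna$end)
    classes <- character(0)
    genes_hit <- character(0)
    for (j in seq_len(nrow(gm$genes))) {
      gn <- gm$genes[j, ]
      if (p0 < gn$start - flank_bp || p0 >= gn$end + flank_bp) next
      cd <- cds_cache[[gn$gene_id]]
      seg <- which(p0 >= cd$start & p0 < cd$end)
      if (length(seg)) {
        if (sum(cd$len) %% 3 != 0) {
          out$unannotatable[i] <- TRUE
          classes <- c(classes, "genic_noncoding")
          genes_hit <- c(genes_hit, gn$gene_id)
          next
        }
        cls <- syn_or_nonsyn(p0, cd, seg, attr(cd, "strand"), refseq,
                             sites$ref[i], sites$alt[i])
        if (is.na(cls)) out$unannotatable[i] <- TRUE
        else classes <- c(classes, cls)
      } else {
        classes <- c(classes, "genic_noncoding")
      }
      genes_hit <- c(genes_hit, gn$gene_id)
    }
    if (length(classes)) {
      out$class[i] <- classes[which.max(sev[classes])]
      out$all_classes[i] <- paste(sort(unique(classes)), collapse = ",")
      out$gene_id[i] <- paste(unique(genes_hit), collapse = ",")
    }
  }
  out
}

# codon-level call for one SNP inside a CDS segment
syn_or_nonsyn <- function(p0, cd, seg, strand, refseq, ref, alt) {
  if (is.null(refseq)) return(NA_character_)
  offset <- if (strand == "+") cd$cum[seg] + (p0 - cd$start[seg])
  else cd$cum[seg] + (cd$end[seg] - 1L - p0)
  codon_i <- offset %/% 3L
  within <- offset %% 3L
  # genomic positions (0-based) of the codon in translation order
  tr_pos <- vapply((codon_i * 3L):(codon_i * 3L + 2L), function(o) {
    s <- max(which(cd$cum <= o))
    if (strand == "+") cd$start[s] + (o - cd$cum[s])
    else cd$end[s] - 1L - (o - cd$cum[s])
  }, numeric(1))
  bases <- vapply(tr_pos, function(pp)
    substr(refseq, pp + 1L, pp + 1L), character(1))
  if (strand == "-") bases <- unname(COMPLEMENT[bases])
  ref_c <- if (strand == "+") ref else unname(COMPLEMENT[ref])
  alt_c <- if (strand == "+") alt else unname(COMPLEMENT[alt])
  if (!identical(bases[within + 1L], ref_c)) {
    # reference FASTA and VCF ref disagree; still classify using the FASTA
    ref_c <- bases[within + 1L]
  }
  if (!alt_c %in% BASES) return(NA_character_)
  codon_ref <- paste(bases, collapse = "")
  bases[within + 1L] <- alt_c
  codon_alt <- paste(bases, collapse = "")
  aa_ref <- translate_codon(codon_ref)
  aa_alt <- translate_codon(codon_alt)
  if (is.na(aa_ref) || is.na(aa_alt)) return(NA_character_)
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

# potential synonymous sites of one codon (Nei-Gojobori counting)
syn_sites_codon <- function(codon) {
  aa <- translate_codon(codon)
  if (is.na(aa)) return(NA_real_)
  s <- 0
  for (pos in 1:3) {
    b <- substr(codon, pos, pos)
    for (nb in setdiff(BASES, b)) {
      alt <- codon
      substr(alt, pos, pos) <- nb
      if (identical(translate_codon(alt), aa)) s <- s + 1 / 3
    }
  }
  s
}

#' Per-class nucleotide diversity and ratio table
#'
#' Per-class per-bp pi over each class's site complement: synonymous and
#' nonsynonymous diversity are divided by the potential synonymous and
#' nonsynonymous site counts of the reference CDS (Nei-Gojobori counting);
#' genic-noncoding and intergenic diversity by their genomic footprints.
#' The reported `dn_ds` is a ratio of per-site diversities (piN/piS-style),
#' not a codon-model omega.
#'
#' @param g a `genotype_matrix`.
#' @param annotations output of [annotate_snps()].
#' @param gm the `gene_model_set` used for annotation.
#' @param subpop optional subpopulation restriction.
#' @param flank_bp flank width used during annotation.
#' @return list with `by_class` (class, n_snps, pi_total, footprint_bp,
#'   pi_per_bp) and `ratios` (`dn_ds`, `noncoding_coding`); undefined ratios
#'   are NA.
#' @export
diversity_by_class <- function(g, annotations, gm, subpop = NULL,
                               flank_bp = 2000L) {
  d <- g$dosage
  if (!is.null(subpop)) d <- d[g$subpop == subpop, , drop = FALSE]
  ss <- site_summaries(d)
  # footprints
  cds_bp <- sum(gm$cds$end - gm$cds$start)
  syn_bp <- nonsyn_bp <- 0
  if (!is.null(gm$seq)) {
    for (gid in gm$genes$gene_id) {
      cd <- cds_in_order(gm, gid)
      strand <- attr(cd, "strand")
      seqc <- gm$seq[[1]]
      cds_seq <- paste(vapply(seq_len(nrow(cd)), function(s) {
        sub <- substr(seqc, cd$start[s] + 1L, cd$end[s])
        sub
      }, character(1)), collapse = "")
      if (strand == "-")
        cds_seq <- paste(rev(unname(COMPLEMENT[strsplit(cds_seq, "")[[1]]])),
                         collapse = "")
      ncod <- nchar(cds_seq) %/% 3L
      for (ci in seq_len(ncod)) {
        syn <- syn_sites_codon(substr(cds_seq, 3 * ci - 2, 3 * ci))
        if (!is.na(syn)) {
          syn_bp <- syn_bp + syn
          nonsyn_bp <- nonsyn_bp + (3 - syn)
        }
      }
    }
  }
  # genic-noncoding footprint: union of flanked gene spans minus CDS
  reg_len <- if (!is.na(gm$region_length)) gm$region_length
  else max(gm$genes$end, gm$ncrna$end, g$sites$pos) + flank_bp
  cov <- rep(FALSE, reg_len)
  for (j in seq_len(nrow(gm$genes)))
    cov[max(1, gm$genes$start[j] - flank_bp + 1):
          min(reg_len, gm$genes$end[j] + flank_bp)] <- TRUE
  incds <- rep(FALSE, reg_len)
  for (j in seq_len(nrow(gm$cds)))
    incds[(gm$cds$start[j] + 1):gm$cds$end[j]] <- TRUE
  genic_nc_bp <- sum(cov & !incds)
  intergenic_bp <- reg_len - sum(cov)
  foot <- c(synonymous = syn_bp, nonsynonymous = nonsyn_bp,
            genic_noncoding = genic_nc_bp, intergenic = intergenic_bp)
  classes <- names(foot)
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    ix <- which(annotations$class == cl)
    pt <- sum(ss$pi[ix], na.rm = TRUE)
    data.frame(class = cl, n_snps = length(ix), pi_total = pt,
               footprint_bp = foot[[cl]],
               pi_per_bp = if (foot[[cl]] > 0) pt / foot[[cl]] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  geti <- function(cl) by_class$pi_per_bp[by_class$class == cl]
  coding_pi <- {
    ctot <- sum(by_class$pi_total[by_class$class %in%
                                    c("synonymous", "nonsynonymous")])
    if (cds_bp > 0) ctot / cds_bp else NA_real_
  }
  nc_pi <- {
    ntot <- sum(by_class$pi_total[by_class$class %in%
                                    c("genic_noncoding", "intergenic")])
    den <- genic_nc_bp + intergenic_bp
    if (den > 0) ntot / den else NA_real_
  }
  ratios <- c(
    dn_ds = if (!is.na(geti("synonymous")) && geti("synonymous") > 0)
      geti("nonsynonymous") / geti("synonymous") else NA_real_,
    noncoding_coding = if (!is.na(coding_pi) && coding_pi > 0)
      nc_pi / coding_pi else NA_real_)
  list(by_class = by_class, ratios = ratios)
}
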