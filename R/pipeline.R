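# End-to-end orchestration on synthetic data: simulate a full-sib family,
# scan QTL, test hotspots, project SHRs, simulate the association panel on
# those SHRs, run selection scans, LD, mixed-model association and the
# epistasis scan, then summarise against the planted truth.
#
# Every stage derives its RNG seed from the master seed, writes its outputs
# (TSV/BED/VCF/JSON) into its own subdirectory, and reads its inputs from
# the upstream stage's files, so stages are resumable and reruns with the
# same configuration are byte-identical.

#' Default pipeline configuration
#'
#' Desk-scale end-to-end scenario: a 300-progeny family with three planted
#' QTN (two co-localised on one LG), a 150-member three-subpopulation panel
#' on the projected SHRs with one planted sweep, additive/dominant/
#' pleiotropic causal SNPs and one dominance-by-dominance epistatic pair.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @return nested configuration list (can be serialised to YAML).
#' @export
pipeline_config <- function(seed = 1L, out_dir = "linkld_out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "qtl", "hotspots", "shr", "panel", "popgen",
               "ld", "assoc", "epistasis", "report"),
    family = list(n_progeny = 300L, n_lg = 19L, markers_per_lg = 15L,
                  mean_interval_cm = 2.3, n_timepoints = 12L,
                  ar1_rho = 0.6, missing_rate = 0.02),
    family_qtns = list(
      list(trait = "V", pve = 0.15, pve_class = "increase-then-level",
           lg = "LG04", cm = 20),
      list(trait = "BD", pve = 0.12, pve_class = "increasing",
           lg = "LG04", cm = 20.5),
      list(trait = "H", pve = 0.12, pve_class = "level",
           lg = "LG02", cm = 12)),
    qtl = list(step = 1, threshold = 3, n_perm = 1000, alpha = 0.05),
    hotspots = list(n_perm = 1000, alpha = 0.05, bin_cm = 1),
    panel = list(sizes = c(S = 60L, NW = 40L, NE = 50L), f = 0.10,
                 snps_per_region = 2000L, missing_rate = 0.02,
                 min_region_bp = 20000L, max_region_bp = 30000L,
                 h2_poly = 0.3,
                 n_founder_haps = 16L,
                 sweep = list(subpop = "NW", rho_sweep = 0.05),
                 causal = list(
                   list(trait = "V", pve = 0.15,
                        pve_class = "increase-then-level", dom_ratio = 0),
                   list(trait = "BD", pve = 0.12, pve_class = "level",
                        dom_ratio = Inf),
                   list(trait = "H", pve = 0.12, pve_class = "increasing",
                        dom_ratio = 0.5)),
                 epi = list(trait = "BD", pve = 0.10, type = "dxd")),
    popgen = list(window_bp = 250L, flank_bp = 10000L, q = 0.01,
                  max_gap = 1L),
    ld = list(n_perm = 1000, r2_min = 0.75, p_max = 1e-3, max_pairs = 30L,
              region = 1L),
    assoc = list(alpha_effect = 0.001),
    epistasis = list(alpha = 0.001, max_candidates = 40L),
    filter = list(max_missing = 0.10, min_maf = 0.05, flank_bp = 2000L))
}

stage_seed <- function(cfg, stage) {
  offs <- c(simulate = 101L, qtl = 202L, hotspots = 303L, shr = 404L,
            panel = 505L, popgen = 606L, ld = 707L, assoc = 808L,
            epistasis = 909L, report = 0L)
  (cfg$seed * 1000L + offs[[stage]]) %% .Machine$integer.max
}

need_file <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream output '", basename(path),
         "'; run stage '", stage, "' first", call. = FALSE)
  path
}

wtsv <- function(x, path) utils::write.table(x, path, sep = "\t",
                                             quote = FALSE, row.names = FALSE)
rtsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Run the pipeline
#'
#' Executes the configured stages in order. Each stage writes its outputs
#' under `out_dir/<stage>/`; later stages read the files of earlier ones, so
#' a subset of stages can be rerun against existing outputs.
#'
#' @param config configuration list from [pipeline_config()], or the path of
#'   a YAML file containing one.
#' @param stages stages to execute (default: all configured stages).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = config$stages) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(yaml::as.yaml(config), file.path(config$out_dir, "config.yaml"))
  for (st in stages) {
    f <- switch(st,
                simulate = stage_simulate, qtl = stage_qtl,
                hotspots = stage_hotspots, shr = stage_shr,
                panel = stage_panel, popgen = stage_popgen,
                ld = stage_ld, assoc = stage_assoc,
                epistasis = stage_epistasis, report = pipeline_report,
                stop("unknown stage: ", st))
    message("[linkLD] stage: ", st)
    f(config)
  }
  invisible(config$out_dir)
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "simulate")
  fc <- do.call(family_config,
                c(cfg$family, list(seed = stage_seed(cfg, "simulate"))))
  qtns <- lapply(cfg$family_qtns, function(q) do.call(qtn_spec, q))
  fam <- simulate_fullsib(fc, qtns)
  write_linkage_dataset(fam, file.path(d, "map.tsv"),
                        file.path(d, "calls.tsv"), file.path(d, "pheno.tsv"))
  anchors <- simulate_anchors(fam$map, seed = stage_seed(cfg, "simulate"))
  wtsv(anchors, file.path(d, "anchors.tsv"))
  truth <- attr(fam, "truth")
  jsonlite::write_json(list(qtn = truth$qtn, effects = truth$effects,
                            seed = truth$seed),
                       file.path(d, "truth_family.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(d)
}

stage_qtl <- function(cfg) {
  sd_ <- stage_dir(cfg, "simulate")
  d <- stage_dir(cfg, "qtl")
  dat <- read_linkage_inputs(need_file(file.path(sd_, "map.tsv"), "simulate"),
                             file.path(sd_, "calls.tsv"),
                             file.path(sd_, "pheno.tsv"))
  sets <- phenotype_sets(dat)
  qtl_all <- NULL
  prof_all <- NULL
  thr_all <- NULL
  for (i in seq_len(nrow(sets))) {
    tr <- sets$trait[i]; tp <- sets$timepoint[i]
    thr <- permutation_threshold(dat, tr, tp, n_perm = cfg$qtl$n_perm,
                                 alpha = cfg$qtl$alpha, step = cfg$qtl$step,
                                 seed = stage_seed(cfg, "qtl") + i)
    scan <- mqm_scan(dat, tr, tp, step = cfg$qtl$step,
                     threshold = max(cfg$qtl$threshold, 0))
    qtl_all <- rbind(qtl_all, scan$qtl)
    thr_all <- rbind(thr_all, data.frame(trait = tr, timepoint = tp,
                                         threshold = as.numeric(thr),
                                         stringsAsFactors = FALSE))
    gg <- scan$grid
    gg$trait <- tr; gg$timepoint <- tp
    prof_all <- rbind(prof_all, gg)
  }
  wtsv(qtl_all, file.path(d, "qtl.tsv"))
  wtsv(thr_all, file.path(d, "thresholds.tsv"))
  wtsv(prof_all, file.path(d, "lod_profiles.tsv"))
  invisible(d)
}

stage_hotspots <- function(cfg) {
  qd <- stage_dir(cfg, "qtl")
  d <- stage_dir(cfg, "hotspots")
  qtl <- rtsv(need_file(file.path(qd, "qtl.tsv"), "qtl"))
  map <- rtsv(need_file(file.path(cfg$out_dir, "simulate", "map.tsv"),
                        "simulate"))
  hs <- hotspot_test(qtl, map, n_perm = cfg$hotspots$n_perm,
                     alpha = cfg$hotspots$alpha,
                     bin_cm = cfg$hotspots$bin_cm,
                     seed = stage_seed(cfg, "hotspots"))
  wtsv(hs$bins, file.path(d, "hotspot_bins.tsv"))
  jsonlite::write_json(list(threshold = as.numeric(hs$threshold),
                            n_perm = hs$n_perm, alpha = hs$alpha,
                            n_hotspots = sum(hs$bins$hotspot)),
                       file.path(d, "hotspots.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(d)
}

stage_shr <- function(cfg) {
  qd <- stage_dir(cfg, "qtl")
  sd_ <- stage_dir(cfg, "simulate")
  d <- stage_dir(cfg, "shr")
  qtl <- rtsv(need_file(file.path(qd, "qtl.tsv"), "qtl"))
  anchors <- rtsv(need_file(file.path(sd_, "anchors.tsv"), "simulate"))
  regions <- cluster_colocalized(qtl)
  wtsv(regions, file.path(d, "overlap_regions.tsv"))
  pr <- project_regions(regions, anchors)
  wtsv(pr$shr, file.path(d, "shr.tsv"))
  if (nrow(pr$shr))
    write_intervals(data.frame(chrom = pr$shr$chrom, start = pr$shr$start,
                               end = pr$shr$end, name = pr$shr$name),
                    file.path(d, "shr.bed"))
  else file.create(file.path(d, "shr.bed"))
  jsonlite::write_json(
    list(n_overlap_regions = nrow(regions), n_shr = nrow(pr$shr),
         failed = if (is.null(pr$failed)) list() else pr$failed),
    file.path(d, "shr.json"), auto_unbox = TRUE, digits = NA)
  invisible(d)
}

stage_panel <- function(cfg) {
  shrd <- stage_dir(cfg, "shr")
  d <- stage_dir(cfg, "panel")
  shr <- rtsv(need_file(file.path(shrd, "shr.tsv"), "shr"))
  pc <- cfg$panel
  if (nrow(shr) == 0) stop("no SHRs available; nothing to simulate a panel on")
  # the resequenced target is a core interval around each SHR centre, so
  # SNP density stays realistic whatever the projected SHR span
  ctr <- (shr$start + shr$end) %/% 2L
  half <- pmin(pmax(shr$end - shr$start, pc$min_region_bp),
               pc$max_region_bp) %/% 2L
  flank <- cfg$popgen$flank_bp
  regions <- data.frame(chrom = shr$chrom,
                        start = pmax(0L, ctr - half - flank),
                        end = ctr + half + flank,
                        name = shr$name, stringsAsFactors = FALSE)
  pcfg <- panel_config(sizes = unlist(pc$sizes), f = pc$f,
                       snps_per_region = pc$snps_per_region,
                       missing_rate = pc$missing_rate,
                       h2_poly = pc$h2_poly,
                       n_founder_haps = pc$n_founder_haps,
                       seed = stage_seed(cfg, "panel"))
  qtns <- lapply(pc$causal, function(q)
    qtn_spec(trait = q$trait, pve = q$pve, pve_class = q$pve_class,
             dom_ratio = q$dom_ratio))
  sw <- sweep_spec(regions$chrom[1], regions$start[1],
                   regions$start[1] + (regions$end[1] - regions$start[1]) %/% 3,
                   pc$sweep$subpop, pc$sweep$rho_sweep)
  ep <- epi_spec(siteA = NA, siteB = NA, trait = pc$epi$trait,
                 pve = pc$epi$pve, type = pc$epi$type)
  sim <- simulate_panel(pcfg, qtns = qtns, sweeps = list(sw),
                        epi_pairs = list(ep), regions = regions)
  ep_res <- sim$truth$epi_pairs[[1]]
  write_vcf(sim$genotypes, file.path(d, "panel.vcf"))
  wtsv(sim$phenotypes, file.path(d, "panel_pheno.tsv"))
  wtsv(data.frame(individual = rownames(sim$genotypes$dosage),
                  subpop = unname(sim$genotypes$subpop)),
       file.path(d, "subpops.tsv"))
  wtsv(regions, file.path(d, "panel_regions.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(causal_sites = sim$genotypes$sites$id[
           vapply(truth$qtns, function(q) q$site, numeric(1))],
         effects = truth$effects,
         sweep = truth$sweeps[[1]],
         epi = list(siteA = sim$genotypes$sites$id[ep_res$siteA],
                    siteB = sim$genotypes$sites$id[ep_res$siteB],
                    trait = ep_res$trait, pve = ep_res$pve,
                    type = ep_res$type),
         seed = truth$seed),
    file.path(d, "truth_panel.json"), auto_unbox = TRUE, digits = NA)
  invisible(d)
}

read_panel <- function(cfg) {
  pd <- file.path(cfg$out_dir, "panel")
  subp <- rtsv(need_file(file.path(pd, "subpops.tsv"), "panel"))
  g <- read_vcf(need_file(file.path(pd, "panel.vcf"), "panel"),
                filter = do.call(filter_config, cfg$filter),
                subpop = stats::setNames(subp$subpop, subp$individual))
  ph <- rtsv(file.path(pd, "panel_pheno.tsv"))
  list(g = g, pheno = ph,
       regions = rtsv(file.path(pd, "panel_regions.tsv")))
}

stage_popgen <- function(cfg) {
  d <- stage_dir(cfg, "popgen")
  pan <- read_panel(cfg)
  g <- pan$g
  windows <- tile_windows(pan$regions, size = cfg$popgen$window_bp,
                          flank = cfg$popgen$flank_bp)
  pops <- unique(g$subpop)
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  all_regions <- NULL
  for (pr in pairs) {
    st <- window_stats(g, windows, objective = pr[1], reference = pr[2])
    st <- joint_outlier_windows(st, q = cfg$popgen$q)
    wtsv(st, file.path(d, sprintf("windows_%s_vs_%s.tsv", pr[1], pr[2])))
    reg <- merge_regions(st, max_gap = cfg$popgen$max_gap,
                         window_size = cfg$popgen$window_bp)
    reg <- confirm_with_tajima(reg, st)
    all_regions <- rbind(all_regions, reg)
  }
  if (is.null(all_regions) || nrow(all_regions) == 0) {
    file.create(file.path(d, "selective_regions.bed"))
    wtsv(data.frame(), file.path(d, "selective_regions.tsv"))
  } else {
    wtsv(all_regions, file.path(d, "selective_regions.tsv"))
    write_intervals(data.frame(chrom = all_regions$chrom,
                               start = all_regions$start,
                               end = all_regions$end,
                               name = paste0(all_regions$region, "_",
                                             all_regions$objective, "_vs_",
                                             all_regions$reference)),
                    file.path(d, "selective_regions.bed"))
  }
  wtsv(classify_fixation(g), file.path(d, "fixation_classes.tsv"))
  invisible(d)
}

stage_ld <- function(cfg) {
  d <- stage_dir(cfg, "ld")
  pan <- read_panel(cfg)
  g <- pan$g
  rg <- pan$regions[cfg$ld$region, ]
  in_region <- which(g$sites$chrom == rg$chrom &
                       g$sites$pos - 1L >= rg$start &
                       g$sites$pos - 1L < rg$end)
  ld <- pairwise_r2(g, sites = in_region, n_perm = cfg$ld$n_perm,
                    max_pairs = cfg$ld$max_pairs,
                    seed = stage_seed(cfg, "ld"))
  wtsv(ld$pairs, file.path(d, "ld_pairs.tsv"))
  blocks <- detect_blocks(ld, r2_min = cfg$ld$r2_min, p_max = cfg$ld$p_max)
  wtsv(blocks, file.path(d, "ld_blocks.tsv"))
  if (nrow(blocks))
    write_intervals(data.frame(chrom = blocks$chrom, start = blocks$start,
                               end = blocks$end, name = blocks$block),
                    file.path(d, "ld_blocks.bed"))
  else file.create(file.path(d, "ld_blocks.bed"))
  dec <- tryCatch(fit_decay(ld), error = function(e) NULL,
                  warning = function(w) suppressWarnings(fit_decay(ld)))
  jsonlite::write_json(
    if (is.null(dec)) list(fit = "failed") else
      list(rho = dec$rho, decay_dist = dec$decay_dist,
           decay_note = dec$decay_note, n_pairs = dec$n_pairs,
           model = "Hill-Weir"),
    file.path(d, "ld_decay.json"), auto_unbox = TRUE, digits = NA)
  invisible(d)
}

stage_assoc <- function(cfg) {
  d <- stage_dir(cfg, "assoc")
  pan <- read_panel(cfg)
  g <- pan$g
  thr <- compute_thresholds(ncol(g$dosage))
  K <- suppressWarnings(estimate_kinship(g))
  sets <- phenotype_sets(pan$pheno)
  rec_all <- NULL
  for (i in seq_len(nrow(sets))) {
    rec <- mlm_scan(g, pan$pheno, sets$trait[i], sets$timepoint[i], K = K)
    rec$lambda_gc <- attr(rec, "lambda_gc")
    rec_all <- rbind(rec_all, rec)
  }
  sig <- rec_all[!is.na(rec_all$p) & rec_all$p <= thr$suggestive, ]
  # effect classification for suggestive associations
  if (nrow(sig)) {
    cls <- vapply(seq_len(nrow(sig)), function(k) {
      ce <- tryCatch(classify_effect(g, pan$pheno, sig$trait[k],
                                     sig$timepoint[k], sig$id[k],
                                     alpha = cfg$assoc$alpha_effect),
                     error = function(e) list(class = "none", a = NA, d = NA))
      paste(ce$class, signif(ce$a, 4), signif(ce$d, 4), sep = "|")
    }, character(1))
    parts <- do.call(rbind, strsplit(cls, "|", fixed = TRUE))
    sig$effect_class <- parts[, 1]
    sig$a <- suppressWarnings(as.numeric(parts[, 2]))
    sig$d <- suppressWarnings(as.numeric(parts[, 3]))
  }
  wtsv(rec_all, file.path(d, "associations.tsv"))
  wtsv(sig, file.path(d, "significant.tsv"))
  jsonlite::write_json(list(n_markers = thr$n_markers,
                            suggestive = thr$suggestive,
                            significant = thr$significant,
                            n_sets = nrow(sets)),
                       file.path(d, "thresholds.json"), auto_unbox = TRUE,
                       digits = NA)
  # lead-SNP clusters for the densest set
  if (nrow(sig)) {
    setlab <- paste0(sig$trait, ":", sig$timepoint)
    top <- names(sort(table(setlab), decreasing = TRUE))[1]
    ss <- strsplit(top, ":")[[1]]
    recs <- rec_all[rec_all$trait == ss[1] & rec_all$timepoint == ss[2], ]
    leads <- lead_snp_clusters(recs, g, threshold = thr$suggestive)
    wtsv(leads, file.path(d, "lead_snps.tsv"))
  }
  invisible(d)
}

stage_epistasis <- function(cfg) {
  d <- stage_dir(cfg, "epistasis")
  pan <- read_panel(cfg)
  g <- pan$g
  tj <- jsonlite::read_json(need_file(
    file.path(cfg$out_dir, "panel", "truth_panel.json"), "panel"))
  tr <- tj$epi$trait
  tp <- utils::tail(unique(pan$pheno$timepoint), 1)
  thr <- compute_thresholds(ncol(g$dosage))
  assoc_path <- file.path(cfg$out_dir, "assoc", "associations.tsv")
  cand <- if (file.exists(assoc_path)) {
    aa <- rtsv(assoc_path)
    aa <- aa[aa$trait == tr & !is.na(aa$p), ]
    aa$id[order(aa$p)][seq_len(min(cfg$epistasis$max_candidates, nrow(aa)))]
  } else g$sites$id[seq_len(min(cfg$epistasis$max_candidates,
                                ncol(g$dosage)))]
  cand <- unique(c(cand, unlist(tj$epi[c("siteA", "siteB")])))
  cand <- cand[cand %in% g$sites$id]
  res <- epistasis_scan(g, pan$pheno, tr, tp, candidates = cand,
                        alpha = cfg$epistasis$alpha)
  wtsv(res, file.path(d, "epistasis.tsv"))
  if (nrow(res))
    wtsv(res[, c("snpA", "snpB", "p_int", "c")],
         file.path(d, "epistasis_edges.tsv"))
  invisible(d)
}

#' Summarise pipeline outputs (with truth recovery when available)
#'
#' Collects the per-stage result files into a human-readable text summary
#' and a JSON report; when truth files are present, adds recovery metrics
#' (planted family QTN covered by an SHR, sweep windows flagged, causal SNPs
#' recovered at the suggestive threshold, epistatic pair retained).
#'
#' @param config the pipeline configuration (list or YAML path).
#' @return the report list, invisibly.
#' @export
pipeline_report <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  d <- stage_dir(cfg, "report")
  rep_ <- list()
  gf <- function(...) file.path(cfg$out_dir, ...)
  if (file.exists(gf("qtl", "qtl.tsv"))) {
    qtl <- rtsv(gf("qtl", "qtl.tsv"))
    rep_$n_qtl <- nrow(qtl)
  }
  if (file.exists(gf("shr", "shr.tsv"))) {
    shr <- rtsv(gf("shr", "shr.tsv"))
    rep_$n_shr <- nrow(shr)
    or_ <- rtsv(gf("shr", "overlap_regions.tsv"))
    rep_$n_overlap_regions <- nrow(or_)
  }
  if (file.exists(gf("hotspots", "hotspots.json")))
    rep_$n_hotspot_bins <-
      jsonlite::read_json(gf("hotspots", "hotspots.json"))$n_hotspots
  if (file.exists(gf("popgen", "selective_regions.tsv"))) {
    sel <- tryCatch(rtsv(gf("popgen", "selective_regions.tsv")),
                    error = function(e) data.frame())
    rep_$n_selective_regions <- nrow(sel)
    rep_$n_confirmed_regions <- if (nrow(sel)) sum(sel$confirmed) else 0L
  }
  if (file.exists(gf("ld", "ld_blocks.tsv")))
    rep_$n_ld_blocks <- nrow(rtsv(gf("ld", "ld_blocks.tsv")))
  if (file.exists(gf("assoc", "significant.tsv"))) {
    sig <- tryCatch(rtsv(gf("assoc", "significant.tsv")),
                    error = function(e) data.frame())
    rep_$n_suggestive_associations <- nrow(sig)
    if (nrow(sig) && "effect_class" %in% names(sig))
      rep_$associations_by_class <- as.list(table(sig$effect_class))
  }
  if (file.exists(gf("epistasis", "epistasis.tsv")))
    rep_$n_epistatic_pairs <- nrow(rtsv(gf("epistasis", "epistasis.tsv")))
  # truth recovery
  if (file.exists(gf("simulate", "truth_family.json")) &&
      file.exists(gf("qtl", "qtl.tsv"))) {
    tf <- jsonlite::read_json(gf("simulate", "truth_family.json"),
                              simplifyVector = TRUE)
    qtl <- rtsv(gf("qtl", "qtl.tsv"))
    if (!is.null(tf$qtn) && nrow(qtl)) {
      hit <- vapply(seq_len(nrow(tf$qtn)), function(i)
        any(qtl$lg == tf$qtn$lg[i] & qtl$trait == tf$qtn$trait[i] &
              qtl$ci_lo <= tf$qtn$cm[i] & qtl$ci_hi >= tf$qtn$cm[i]),
        logical(1))
      rep_$family_qtn_recovered <- sum(hit)
      rep_$family_qtn_total <- nrow(tf$qtn)
    }
  }
  if (file.exists(gf("panel", "truth_panel.json")) &&
      file.exists(gf("assoc", "significant.tsv"))) {
    tp_ <- jsonlite::read_json(gf("panel", "truth_panel.json"),
                               simplifyVector = TRUE)
    sig <- tryCatch(rtsv(gf("assoc", "significant.tsv")),
                    error = function(e) data.frame())
    if (nrow(sig))
      rep_$causal_snps_recovered <- sum(tp_$causal_sites %in% sig$id)
    rep_$causal_snps_total <- length(tp_$causal_sites)
    if (file.exists(gf("epistasis", "epistasis.tsv"))) {
      ep <- rtsv(gf("epistasis", "epistasis.tsv"))
      rep_$epi_pair_recovered <- any(
        (ep$snpA == tp_$epi$siteA & ep$snpB == tp_$epi$siteB) |
          (ep$snpA == tp_$epi$siteB & ep$snpB == tp_$epi$siteA))
    }
  }
  jsonlite::write_json(rep_, file.path(d, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  txt <- c("linkLD pipeline report",
           strrep("=", 22),
           vapply(names(rep_), function(k)
             sprintf("%-28s %s", k, paste(unlist(rep_[[k]]), collapse = " ")),
             character(1)))
  writeLines(txt, file.path(d, "report.txt"))
  invisible(rep_)
}
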