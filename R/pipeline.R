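#' Profiling options
#'
#' Every analysis threshold surfaces here with its standard default:
#' variant filter (VAF >= 0.05, depth >= 100, exonic/splice), clonality
#' alpha 0.05, MATH minimum 3 variants, signature minimum 20 SNVs,
#' purity anchoring tolerance 0.15, subclonal-CN delta 0.25, WGD ploidy
#' 3.0, arm span 0.80, HRD lengths 15/10/3/1 Mb, diploid FGA baseline,
#' TVAF ratio orientation.
#'
#' @param min_vaf,min_depth,allowed_regions Variant filter settings.
#' @param clonality_alpha Subclonality significance level.
#' @param math_min_variants Minimum VAFs for MATH.
#' @param min_snvs_signature Minimum SNVs for a signature fit.
#' @param purity_tolerance Purity anchoring tolerance.
#' @param subclonal_delta Non-integrality threshold for subclonal CN.
#' @param wgd_threshold Ploidy at which WGD is called.
#' @param arm_span Arm-event span threshold.
#' @param loh_min_mb,lst_flank_mb,lst_smooth_mb,tai_min_mb HRD lengths
#'   (Mb).
#' @param fga_baseline `"diploid"` or `"ploidy"`.
#' @param tvaf_mode `"ratio"` or `"product"`.
#' @param max_cn Largest copy number in the purity/ploidy grid.
#' @return A named list of options.
#' @export
profile_options <- function(min_vaf = 0.05, min_depth = 100,
                            allowed_regions = c("exonic", "splice"),
                            clonality_alpha = 0.05,
                            math_min_variants = 3,
                            min_snvs_signature = 20,
                            purity_tolerance = 0.15,
                            subclonal_delta = 0.25,
                            wgd_threshold = 3.0,
                            arm_span = 0.80,
                            loh_min_mb = 15, lst_flank_mb = 10,
                            lst_smooth_mb = 3, tai_min_mb = 1,
                            fga_baseline = c("diploid", "ploidy"),
                            tvaf_mode = c("ratio", "product"),
                            max_cn = 8) {
  list(min_vaf = min_vaf, min_depth = min_depth,
       allowed_regions = allowed_regions,
       clonality_alpha = clonality_alpha,
       math_min_variants = math_min_variants,
       min_snvs_signature = min_snvs_signature,
       purity_tolerance = purity_tolerance,
       subclonal_delta = subclonal_delta,
       wgd_threshold = wgd_threshold, arm_span = arm_span,
       loh_min_mb = loh_min_mb, lst_flank_mb = lst_flank_mb,
       lst_smooth_mb = lst_smooth_mb, tai_min_mb = tai_min_mb,
       fga_baseline = match.arg(fga_baseline),
       tvaf_mode = match.arg(tvaf_mode), max_cn = max_cn)
}

#' Profile one sample into its biomarker record
#'
#' Runs the per-sample pipeline in order: variant filtering, purity/
#' ploidy fitting (skipped when segments arrive pre-fitted with
#' `total_cn`/`minor_cn`), local copy-number annotation, clonality
#' classification, TMB and scTMB, MATH, median TVAF, mutation spectrum
#' and signature refit, ploidy/WGD, HRD scars, genome fractions, arm
#' events, and optional gene-level calls.
#'
#' @param variants Variant tibble ([read_somatic_vcf()] shape).
#' @param segments Segment tibble with logR/BAF (or pre-fitted CN).
#' @param purity Histopathological tumor purity (0, 1].
#' @param callable_mb Callable megabases.
#' @param genome A `genome_model`.
#' @param signatures A `signature_matrix`.
#' @param sample_id Sample identifier carried into the output row.
#' @param genes Optional gene interval tibble for amp/del calls.
#' @param options [profile_options()].
#' @return One-row tibble with the biomarker panel: `sample`, `tmb`,
#'   `sc_tmb`, `math`, `median_tvaf`, `clocklike_sbs1_5`, per-signature
#'   weights, `purity_fit`, `ploidy`, `wgd`, `hrd_loh`, `lst`, `tai`,
#'   `hrd_sum`, `fga`, `subclonal_cn_fraction`, `n_arm_loh`,
#'   `arm_loh`, `arm_deep_loss`, `gene_amp`, `gene_del`, `n_variants`.
#' @export
profile_sample <- function(variants, segments, purity, callable_mb,
                           genome = hetpanel_genome(),
                           signatures = hetpanel_signatures(),
                           sample_id = "sample", genes = NULL,
                           options = profile_options()) {
  if (is.null(purity) || is.na(purity) || purity <= 0 || purity > 1) {
    abort("purity is required and must lie in (0, 1]")
  }
  opt <- options
  flt <- apply_variant_filters(variants, min_vaf = opt$min_vaf,
                               min_depth = opt$min_depth,
                               allowed_regions = opt$allowed_regions)

  prefitted <- all(c("total_cn", "minor_cn") %in% names(segments)) &&
    !anyNA(segments$total_cn)
  if (prefitted) {
    seg <- segments
    if (!"length" %in% names(seg)) seg$length <- seg$end - seg$start + 1
    if (!"continuous_cn" %in% names(seg)) seg$continuous_cn <- seg$total_cn
    purity_fit <- purity
  } else {
    fit <- fit_purity_ploidy(segments, purity_histo = purity,
                             purity_tolerance = opt$purity_tolerance,
                             subclonal_delta = opt$subclonal_delta,
                             max_cn = opt$max_cn)
    seg <- fit$segments
    purity_fit <- fit$solution$purity
  }

  ann <- suppressMessages(annotate_local_copy_number(flt, seg))
  ann <- classify_clonality(ann, purity, alpha = opt$clonality_alpha)

  tmb <- compute_tmb(ann, callable_mb, subset = "all")
  sc_tmb <- compute_tmb(ann, callable_mb, subset = "subclonal")
  math <- compute_math(ann$vaf, min_variants = opt$math_min_variants)
  med_tvaf <- compute_median_tvaf(ann, purity, mode = opt$tvaf_mode)

  spectrum <- suppressMessages(build_mutation_spectrum(ann))
  sig <- fit_signature_weights(spectrum, signatures,
                               min_snvs = opt$min_snvs_signature)

  pw <- compute_ploidy_and_wgd(seg, wgd_threshold = opt$wgd_threshold)
  hrd <- compute_hrd_scores(seg, genome, loh_min_mb = opt$loh_min_mb,
                            lst_flank_mb = opt$lst_flank_mb,
                            lst_smooth_mb = opt$lst_smooth_mb,
                            tai_min_mb = opt$tai_min_mb)
  fr <- compute_cn_fractions(seg, wgd = pw$wgd,
                             baseline = opt$fga_baseline,
                             subclonal_delta = opt$subclonal_delta)
  arms <- call_arm_events(seg, genome, span_threshold = opt$arm_span)
  arm_loh <- paste0(arms$chrom[arms$arm_loh], arms$arm[arms$arm_loh])
  arm_deep <- paste0(arms$chrom[arms$arm_deep_loss],
                     arms$arm[arms$arm_deep_loss])
  gcnv <- if (!is.null(genes)) {
    suppressWarnings(call_gene_cnv(seg, genes))
  } else {
    tibble::tibble(gene = character(), call = character())
  }

  row <- tibble::tibble(
    sample = sample_id,
    tmb = tmb, sc_tmb = sc_tmb, math = math, median_tvaf = med_tvaf,
    clocklike_sbs1_5 = sig$clocklike_sbs1_5,
    purity_fit = purity_fit, ploidy = pw$ploidy, wgd = pw$wgd,
    hrd_loh = hrd$hrd_loh, lst = hrd$lst, tai = hrd$tai,
    hrd_sum = hrd$hrd_sum,
    fga = fr$fga, subclonal_cn_fraction = fr$subclonal_cn_fraction,
    n_arm_loh = length(arm_loh),
    arm_loh = paste(arm_loh, collapse = ","),
    arm_deep_loss = paste(arm_deep, collapse = ","),
    gene_amp = paste(gcnv$gene[gcnv$call == "amplification"],
                     collapse = ","),
    gene_del = paste(gcnv$gene[gcnv$call == "deletion"], collapse = ","),
    n_variants = nrow(ann))
  wtab <- tibble::as_tibble(as.list(sig$weights))
  names(wtab) <- paste0("w_", names(sig$weights))
  dplyr::bind_cols(row, wtab)
}

#' Profile every sample of a cohort
#'
#' Applies [profile_sample()] across a simulated cohort (or a cohort
#' read from disk via [read_cohort()]). With `keep_going = TRUE`
#' (default) a failing sample is recorded in the `failures` attribute
#' instead of aborting the cohort.
#'
#' @param cohort A `cohort_sim` or the list returned by [read_cohort()].
#' @param genome,signatures,genes,options Passed to [profile_sample()].
#' @param keep_going Continue past per-sample failures.
#' @return Biomarker tibble, one row per successful sample, joined with
#'   the cohort metadata (`group`, `purity`, `callable_mb`); attribute
#'   `failures` is a tibble `sample`, `reason`.
#' @export
profile_cohort <- function(cohort, genome = hetpanel_genome(),
                           signatures = hetpanel_signatures(),
                           genes = NULL, options = profile_options(),
                           keep_going = TRUE) {
  meta <- cohort$metadata
  rows <- vector("list", nrow(meta))
  fails <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$sample[i]
    res <- tryCatch(
      profile_sample(cohort$samples[[id]]$variants,
                     cohort$samples[[id]]$segments,
                     purity = meta$purity[i],
                     callable_mb = meta$callable_mb[i],
                     genome = genome, signatures = signatures,
                     sample_id = id, genes = genes, options = options),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (!keep_going) abort(sprintf("sample %s failed: %s", id,
                                     conditionMessage(res)))
      fails[[length(fails) + 1]] <- tibble::tibble(
        sample = id, reason = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(out, meta, by = "sample")
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}

#' Cohort-level analysis: group statistics, pruning, ROC and LOOCV model
#'
#' Reproduces the full cohort stage: Wilcoxon/Fisher group comparisons
#' with Benjamini-Hochberg correction at the configured FDR, per-marker
#' AUC with DeLong intervals, Pearson correlation pruning, and the
#' leave-one-out cross-validated logistic model over the combined
#' feature set (features participating in a flagged correlation pair are
#' dropped, most-correlated first, before fitting).
#'
#' @param biomarkers Biomarker tibble from [profile_cohort()] (or read
#'   with [read_biomarkers()]), containing the label column.
#' @param label Group label column (default `"group"`).
#' @param markers Markers to test (default: the standard panel columns
#'   present).
#' @param binary Markers treated as binary (default `"wgd"`).
#' @param features Candidate features of the combined model (default:
#'   TMB, subclonal-CN fraction, MATH, median TVAF, SBS1+5, ploidy).
#' @param positive Positive class (default: last sorted label).
#' @param fdr False discovery rate (default 0.10).
#' @param r_threshold Correlation pruning threshold (default 0.5).
#' @return A `hetpanel_cohort` object: list with `stats`, `correlations`,
#'   `flagged`, `model` (LOOCV output), `features_used`, and `manifest`.
#' @export
run_cohort <- function(biomarkers, label = "group", markers = NULL,
                       binary = "wgd",
                       features = c("tmb", "subclonal_cn_fraction", "math",
                                    "median_tvaf", "clocklike_sbs1_5",
                                    "ploidy"),
                       positive = NULL, fdr = 0.10, r_threshold = 0.5) {
  t0 <- Sys.time()
  labs <- biomarkers[[label]]
  if (length(unique(labs)) < 2) abort("at least two groups are required")
  if (is.null(markers)) {
    panel <- c("tmb", "sc_tmb", "math", "median_tvaf", "clocklike_sbs1_5",
               "ploidy", "wgd", "hrd_loh", "lst", "tai", "hrd_sum", "fga",
               "subclonal_cn_fraction", "n_arm_loh", "purity")
    markers <- intersect(panel, names(biomarkers))
  }
  binary <- intersect(binary, markers)
  lv <- sort(unique(labs))
  positive <- positive %||% lv[length(lv)]

  stats <- compare_groups(biomarkers, label = label, markers = markers,
                          binary = binary, positive = positive)
  bh <- adjust_bh(stats$p, fdr = fdr)
  stats$q <- bh$q
  stats$significant <- bh$significant
  aucs <- purrr::map_dfr(markers, function(mk) {
    x <- biomarkers[[mk]]
    if (all(is.na(x)) || sd(x, na.rm = TRUE) == 0) {
      return(tibble::tibble(marker = mk, auc = NA_real_,
                            auc_lo = NA_real_, auc_hi = NA_real_))
    }
    a <- roc_auc(as.numeric(x), labs, positive = positive)
    tibble::tibble(marker = mk, auc = a$auc, auc_lo = a$auc_lo,
                   auc_hi = a$auc_hi)
  })
  stats <- dplyr::left_join(stats, aucs, by = "marker")

  num_feats <- intersect(features, names(biomarkers))
  pr <- pearson_prune(biomarkers, features = num_feats,
                      threshold = r_threshold)
  feats <- num_feats
  flagged <- pr$flagged
  while (nrow(flagged) > 0) {
    # drop the feature participating in the strongest remaining pair
    worst <- flagged[which.max(flagged$r), ]
    feats <- setdiff(feats, worst$feature_b)
    flagged <- flagged[flagged$feature_a %in% feats &
                         flagged$feature_b %in% feats, , drop = FALSE]
  }
  if (length(feats) < length(num_feats)) {
    inform(paste0("correlation pruning dropped: ",
                  paste(setdiff(num_feats, feats), collapse = ", ")))
  }

  model <- tryCatch(
    suppressMessages(loocv_logistic(biomarkers, features = feats,
                                    label = label, positive = positive,
                                    max_r = r_threshold)),
    error = function(e) {
      inform(paste0("combined model skipped: ", conditionMessage(e)))
      NULL
    })

  manifest <- list(
    package_version = as.character(utils::packageVersion("hetpanel")),
    n_samples = nrow(biomarkers),
    groups = table(labs),
    positive = positive,
    fdr = fdr, r_threshold = r_threshold,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(stats = stats, correlations = pr$r, flagged = pr$flagged,
                 model = model, features_used = feats,
                 manifest = manifest),
            class = "hetpanel_cohort")
}

#' @export
print.hetpanel_cohort <- function(x, ...) {
  cat(sprintf("<hetpanel_cohort> %d markers, %d significant at FDR %.0f%%\n",
              nrow(x$stats), sum(x$stats$significant),
              100 * x$manifest$fdr))
  if (!is.null(x$model)) {
    cat(sprintf("  LOOCV model (%s): AUC %.2f (%.2f-%.2f)\n",
                paste(x$features_used, collapse = ", "),
                x$model$auc$auc, x$model$auc$auc_lo, x$model$auc$auc_hi))
  }
  invisible(x)
}

#' Write / read a biomarker table
#'
#' One row per sample, missing values as empty strings.
#'
#' @param biomarkers Biomarker tibble.
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_biomarkers <- function(biomarkers, path) {
  readr::write_tsv(biomarkers, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_biomarkers
#' @export
read_biomarkers <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

#' Write the cohort-result tables
#'
#' Emits `cohort_stats.tsv`, `correlations.tsv`, `model_predictions.tsv`
#' and a JSON run summary into `dir`.
#'
#' @param result A `hetpanel_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$stats, file.path(dir, "cohort_stats.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(result$correlations, file.path(dir, "correlations.tsv"),
                   na = "", progress = FALSE)
  if (!is.null(result$model)) {
    readr::write_tsv(result$model$predictions,
                     file.path(dir, "model_predictions.tsv"),
                     progress = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summ <- list(
      manifest = result$manifest[c("package_version", "n_samples",
                                   "positive", "fdr", "r_threshold")],
      significant = result$stats$marker[result$stats$significant],
      features_used = result$features_used,
      model_auc = if (!is.null(result$model)) result$model$auc$auc else NULL)
    jsonlite::write_json(summ, file.path(dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
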