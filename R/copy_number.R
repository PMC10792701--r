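#' Expected logR and BAF under the purity/ploidy mixture model
#'
#' For tumor purity `p`, sample ploidy `psi` and a segment with total
#' copy number `c` and minor copy number `m`, the observed logR and
#' B-allele frequency are modelled as
#' `logR = log2((p*c + 2*(1-p)) / (p*psi + 2*(1-p)))` and
#' `BAF = (p*m + (1-p)) / (p*c + 2*(1-p))`.
#'
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Total copy number.
#' @param ploidy Sample ploidy.
#' @param minor_cn Minor allele copy number.
#' @return Numeric vector.
#' @name cn_model
NULL

#' @rdname cn_model
#' @export
expected_logr <- function(purity, total_cn, ploidy) {
  num <- purity * total_cn + 2 * (1 - purity)
  den <- purity * ploidy + 2 * (1 - purity)
  pmin(pmax(log2(pmax(num, 1e-12) / den), -8), 8)
}

#' @rdname cn_model
#' @export
expected_baf <- function(purity, total_cn, minor_cn) {
  den <- purity * total_cn + 2 * (1 - purity)
  ifelse(den <= 0, 0.5, (purity * minor_cn + (1 - purity)) / den)
}

cn_state_pairs <- function(max_cn = 8) {
  # (c, m) candidates, c ascending then m ascending: which.min tie-breaks
  # to the lowest c, then lowest m
  cs <- unlist(lapply(0:max_cn, function(c) rep(c, floor(c / 2) + 1)))
  ms <- unlist(lapply(0:max_cn, function(c) 0:floor(c / 2)))
  list(c = cs, m = ms)
}

rowmins <- function(M) {
  out <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) out <- pmin(out, M[, k])
  out
}

# capped objective over a ploidy vector at one fixed purity
err_fixed_purity <- function(seg, w, st, purity, psis, logr_sd, baf_sd,
                             residual_cap) {
  ebaf <- expected_baf(purity, st$c, st$m)
  A <- (outer(seg$BAF, ebaf, "-") / baf_sd)^2
  vapply(psis, function(ps) {
    elr <- expected_logr(purity, st$c, ps)
    E <- (outer(seg$logR, elr, "-") / logr_sd)^2 + A
    sum(pmin(rowmins(E), residual_cap) * w)
  }, numeric(1))
}

#' Fit tumor purity and ploidy from segment logR/BAF
#'
#' Grid search over purity (0.10-1.00, step 0.01) and ploidy (1.0-8.0,
#' step 0.1). For every candidate each autosomal segment is assigned the
#' integer state (c, m), `m <= c - m`, minimizing the squared distance to
#' the expected logR and BAF (see [expected_logr()]), each channel
#' standardized by its measurement error scale (`logr_sd`, `baf_sd`);
#' the grid objective is the segment-length-weighted mean of those
#' standardized squared residuals. The inverse-variance weighting
#' matters: the B-allele frequency is measured much more precisely than
#' logR, and without the weighting the classic degenerate
#' half-purity/doubled-ploidy solutions, whose densely spaced expected
#' values can absorb logR noise, can undercut the true optimum. Local
#' optima of the error surface are extracted and the returned solution is
#' the lowest-error optimum whose purity lies within `purity_tolerance`
#' of the histopathological purity; if no optimum is compatible, the
#' global optimum is returned with a warning.
#'
#' Fitted segments gain `total_cn`, `minor_cn`, `continuous_cn` (the
#' closed-form inversion of the logR model, floored at 0) and a
#' `clonality` call: a segment is subclonal when its continuous copy
#' number deviates from the nearest integer by more than
#' `subclonal_delta`.
#'
#' @param segments Segment tibble with `chrom`, `start`, `end`, `length`,
#'   `logR`, `BAF`.
#' @param purity_histo Histopathological purity anchor in (0, 1].
#' @param purity_tolerance Maximum |purity - anchor| for an acceptable
#'   solution (default 0.15).
#' @param subclonal_delta Non-integrality threshold for subclonal CN
#'   (default 0.25).
#' @param max_cn Largest integer copy number considered (default 8).
#' @param logr_sd,baf_sd Measurement error scales used to standardize
#'   the two residual channels (defaults 0.05 and 0.02).
#' @param residual_cap Cap on each segment's standardized squared
#'   residual (default 4.6, i.e. `-2 * log(0.1)`). Segments whose best
#'   integer state remains far off are better read as subclonal copy
#'   number; the cap is the marginal cost of that explanation under an
#'   implicit 10% subclonal prior, and keeps single discordant segments
#'   from steering the whole solution.
#' @param parsimony_window Relative score window (default 0.05) within
#'   which anchored candidates count as tied and the lowest ploidy wins.
#'   Allele-specific grids admit near-exact relabelings onto higher
#'   ploidies (all states multiplied, or affinely shifted near purity
#'   0.5) that genuinely tie the parsimonious solution; preferring the
#'   lower ploidy among ties resolves them the way allele-specific
#'   callers conventionally do.
#' @return List with `solution` (one-row tibble: `purity`, `ploidy`,
#'   `fit_error`, `rank`, `anchored`), `solutions` (all local optima,
#'   ranked), and `segments` (input plus fitted columns).
#' @export
fit_purity_ploidy <- function(segments, purity_histo, purity_tolerance = 0.15,
                              subclonal_delta = 0.25, max_cn = 8,
                              logr_sd = 0.05, baf_sd = 0.02,
                              residual_cap = 4.6, parsimony_window = 0.05) {
  seg <- segments[!is_sex_chrom(segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0) abort("no autosomal segments to fit")
  if (!all(c("logR", "BAF") %in% names(seg)) ||
      anyNA(seg$logR) || anyNA(seg$BAF)) {
    abort("segments must carry complete logR and BAF")
  }
  if (!"length" %in% names(seg)) seg$length <- seg$end - seg$start + 1
  w <- seg$length / sum(seg$length)

  p_grid <- seq(0.10, 1.00, by = 0.01)
  psi_grid <- seq(1.0, 8.0, by = 0.1)
  st <- cn_state_pairs(max_cn)
  cvals <- 0:max_cn
  n_c <- length(cvals)
  n_psi <- length(psi_grid)

  err <- matrix(NA_real_, length(p_grid), n_psi)
  for (pi in seq_along(p_grid)) {
    p <- p_grid[pi]
    ebaf <- expected_baf(p, st$c, st$m)
    A <- (outer(seg$BAF, ebaf, "-") / baf_sd)^2
    amin <- matrix(Inf, nrow(seg), n_c)               # n x (max_cn+1)
    for (k in seq_along(st$c)) {
      ci <- st$c[k] + 1L
      amin[, ci] <- pmin(amin[, ci], A[, k])
    }
    elr <- outer(cvals, psi_grid,
                 function(cc, ps) expected_logr(p, cc, ps)) # C x Psi
    L <- (outer(seg$logR, as.vector(elr), "-") / logr_sd)^2 # n x (C*Psi)
    total <- L + amin[, rep(seq_len(n_c), times = n_psi), drop = FALSE]
    dim(total) <- c(nrow(seg), n_c, n_psi)
    m2 <- total[, 1, ]
    for (ci in 2:n_c) m2 <- pmin(m2, total[, ci, ])
    # capped (Huber-type) residual: a segment whose best integer state
    # is still far off is better explained as subclonal; the cap is
    # -2*log of the implied subclonal prior
    err[pi, ] <- colSums(pmin(m2, residual_cap) * w)
  }

  # local optima: grid points not exceeded by any 8-neighborhood value
  is_opt <- matrix(TRUE, nrow(err), ncol(err))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ri <- seq_len(nrow(err)) + di
    cj <- seq_len(ncol(err)) + dj
    ok_r <- ri >= 1 & ri <= nrow(err)
    ok_c <- cj >= 1 & cj <= ncol(err)
    shifted <- matrix(Inf, nrow(err), ncol(err))
    shifted[ok_r, ok_c] <- err[ri[ok_r], cj[ok_c]]
    is_opt <- is_opt & (err <= shifted)
  }
  idx <- which(is_opt, arr.ind = TRUE)
  sols <- tibble::tibble(
    purity = p_grid[idx[, 1]],
    ploidy = psi_grid[idx[, 2]],
    fit_error = err[idx]
  )
  # always offer the purity-pinned solutions -- the locally best
  # ploidies at the histopathological purity itself -- even when noise
  # tilts the error valley so that no 2-D local optimum sits at the
  # anchor
  pin_i <- which.min(abs(p_grid - purity_histo))
  row <- err[pin_i, ]
  pin_j <- which(row <= c(row[-1], Inf) & row <= c(Inf, row[-n_psi]))
  sols <- dplyr::bind_rows(sols, tibble::tibble(
    purity = p_grid[pin_i], ploidy = psi_grid[pin_j],
    fit_error = row[pin_j]))
  sols <- dplyr::distinct(sols, .data$purity, .data$ploidy,
                          .keep_all = TRUE)
  sols <- dplyr::arrange(sols, .data$fit_error,
                         abs(.data$purity - purity_histo), .data$purity,
                         .data$ploidy)
  sols$rank <- seq_len(nrow(sols))

  # refine candidate ploidies on a 0.01 sub-grid before ranking: the
  # coarse 0.1 ploidy step can favour a harmonic whose (multiplied)
  # ploidy happens to land closer to a grid point than the true value
  refine <- function(tab) {
    for (k in seq_len(nrow(tab))) {
      p <- tab$purity[k]
      psis <- seq(max(tab$ploidy[k] - 0.09, 1), tab$ploidy[k] + 0.09,
                  by = 0.01)
      e <- err_fixed_purity(seg, w, st, p, psis, logr_sd, baf_sd,
                            residual_cap)
      j <- which.min(e)
      tab$ploidy[k] <- psis[j]
      tab$fit_error[k] <- e[j]
    }
    tab
  }

  ok <- abs(sols$purity - purity_histo) <= purity_tolerance
  if (any(ok)) {
    # Among purity-compatible optima, the fit error is mildly inflated
    # by the distance from the histopathological anchor (degenerate
    # harmonics sit farther from it) plus a parsimony prior on ploidy,
    # and near-tied scores resolve to the lower ploidy: a higher-ploidy
    # harmonic can only match the parsimonious solution by re-describing
    # the same data with more states.
    cand <- sols[ok, , drop = FALSE]
    cand <- refine(head(cand, 30))
    score <- cand$fit_error *
      (1 + abs(cand$purity - purity_histo) / purity_tolerance)
    best_score <- min(score)
    # absolute slack 0.1 covers the score jitter that purity/ploidy
    # grid quantization induces between members of an exact-relabeling
    # family
    near <- which(score <= best_score * (1 + parsimony_window) + 0.1)
    pick <- near[order(abs(cand$purity[near] - purity_histo),
                       cand$ploidy[near])[1]]
    chosen <- cand[pick, ]
    chosen$anchored <- TRUE
  } else {
    warn(sprintf(
      "no purity/ploidy optimum within %.2f of histopathological purity %.2f; using global optimum",
      purity_tolerance, purity_histo))
    chosen <- refine(sols[1, ])
    chosen$anchored <- FALSE
  }

  fitted <- assign_cn_states(segments, chosen$purity, chosen$ploidy,
                             subclonal_delta = subclonal_delta,
                             max_cn = max_cn, logr_sd = logr_sd,
                             baf_sd = baf_sd)
  list(solution = chosen, solutions = sols, segments = fitted)
}

#' Assign integer copy-number states at a fixed purity/ploidy
#'
#' Decodes each segment to its best integer state and classifies its
#' clonality. The default classification tests the standardized
#' logR/BAF residual of the best state against its chi-square(2) null:
#' a segment whose observed values are inconsistent with every integer
#' state (`p < alpha`) is called subclonal. This keeps the false-call
#' rate calibrated across purities, unlike a fixed threshold on the
#' continuous copy number, whose noise grows as purity falls.
#' `clonality_method = "delta"` applies that simpler rule instead
#' (subclonal when `|continuous_cn - round(continuous_cn)| >
#' subclonal_delta`).
#'
#' @inheritParams fit_purity_ploidy
#' @param purity,ploidy The purity/ploidy at which to decode states.
#' @param clonality_method `"test"` (default) or `"delta"`.
#' @param alpha Significance level of the subclonality test
#'   (default 0.05).
#' @return `segments` with `total_cn`, `minor_cn`, `continuous_cn`,
#'   `clonality` columns.
#' @export
assign_cn_states <- function(segments, purity, ploidy,
                             subclonal_delta = 0.25, max_cn = 8,
                             logr_sd = 0.05, baf_sd = 0.02,
                             clonality_method = c("test", "delta"),
                             alpha = 0.05) {
  clonality_method <- match.arg(clonality_method)
  st <- cn_state_pairs(max_cn)
  elr <- expected_logr(purity, st$c, ploidy)
  ebaf <- expected_baf(purity, st$c, st$m)
  E <- (outer(segments$logR, elr, "-") / logr_sd)^2 +
    (outer(segments$BAF, ebaf, "-") / baf_sd)^2
  best <- apply(E, 1, which.min)
  r2 <- E[cbind(seq_len(nrow(segments)), best)]
  cont <- (2^segments$logR * (purity * ploidy + 2 * (1 - purity)) -
             2 * (1 - purity)) / purity
  cont <- pmax(cont, 0)
  subclonal <- if (clonality_method == "test") {
    stats::pchisq(r2, df = 2, lower.tail = FALSE) < alpha
  } else {
    abs(cont - round(cont)) > subclonal_delta
  }
  dplyr::mutate(
    segments,
    total_cn = st$c[best],
    minor_cn = st$m[best],
    continuous_cn = cont,
    clonality = ifelse(subclonal, "subclonal", "clonal"))
}

#' Sample ploidy and whole-genome-doubling call
#'
#' Ploidy is the segment-length-weighted mean of the fitted total copy
#' number over autosomes; the sample is called genome-doubled when ploidy
#' reaches `wgd_threshold` (inclusive).
#'
#' @param segments Fitted segment tibble.
#' @param wgd_threshold Ploidy at or above which WGD is called
#'   (default 3.0).
#' @return List `ploidy`, `wgd`.
#' @export
compute_ploidy_and_wgd <- function(segments, wgd_threshold = 3.0) {
  seg <- segments[!is_sex_chrom(segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0) abort("no autosomal segments")
  psi <- weighted.mean(seg$total_cn, seg$length)
  list(ploidy = psi, wgd = psi >= wgd_threshold)
}

# Merge consecutive segments (per chromosome, position-sorted) sharing the
# same (total_cn, minor_cn) state.
merge_cn_segments <- function(segments) {
  seg <- dplyr::arrange(segments, .data$chrom, .data$start)
  seg <- dplyr::group_by(seg, .data$chrom)
  seg <- dplyr::mutate(seg, run = cumsum(
    dplyr::row_number() == 1 |
      .data$total_cn != dplyr::lag(.data$total_cn, default = -1L) |
      .data$minor_cn != dplyr::lag(.data$minor_cn, default = -1L)))
  seg <- dplyr::summarise(
    dplyr::group_by(seg, .data$chrom, .data$run),
    start = min(.data$start), end = max(.data$end),
    total_cn = .data$total_cn[1], minor_cn = .data$minor_cn[1],
    .groups = "drop")
  seg$length <- seg$end - seg$start + 1
  dplyr::arrange(seg, .data$chrom, .data$start)
}

#' Homologous-recombination-deficiency scar scores
#'
#' Computes the three genomic scar counts on autosomal fitted segments
#' (adjacent segments with identical allele-specific state are merged
#' first):
#' * `hrd_loh` - segments with minor copy number 0, total copy number
#'   >= 1, longer than `loh_min_mb` megabases and not spanning the whole
#'   chromosome;
#' * `lst` - after discarding segments shorter than `lst_smooth_mb` Mb
#'   and re-merging, breakpoints between adjacent segments that are both
#'   at least `lst_flank_mb` Mb long;
#' * `tai` - allelic-imbalance segments (minor != total - minor) that
#'   reach a telomere, do not cross the centromere, and are longer than
#'   `tai_min_mb` Mb.
#'
#' `hrd_sum` is their sum.
#'
#' @param segments Fitted segment tibble (`total_cn`, `minor_cn`).
#' @param genome A `genome_model`.
#' @param loh_min_mb,lst_flank_mb,lst_smooth_mb,tai_min_mb Length
#'   thresholds in megabases (defaults 15, 10, 3, 1).
#' @return List `hrd_loh`, `lst`, `tai`, `hrd_sum`.
#' @export
compute_hrd_scores <- function(segments, genome, loh_min_mb = 15,
                               lst_flank_mb = 10, lst_smooth_mb = 3,
                               tai_min_mb = 1) {
  seg <- segments[!is_sex_chrom(segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0) {
    return(list(hrd_loh = 0L, lst = 0L, tai = 0L, hrd_sum = 0L))
  }
  merged <- merge_cn_segments(seg)
  extent <- dplyr::summarise(dplyr::group_by(merged, .data$chrom),
                             chrom_min = min(.data$start),
                             chrom_max = max(.data$end), .groups = "drop")
  merged <- dplyr::left_join(merged, extent, by = "chrom")

  whole_chrom <- merged$start <= merged$chrom_min &
    merged$end >= merged$chrom_max
  hrd_loh <- sum(merged$minor_cn == 0 & merged$total_cn >= 1 &
                   merged$length > loh_min_mb * 1e6 & !whole_chrom)

  # LST: smooth sub-3Mb segments away, re-merge, count large flanked joins
  sm <- merged[merged$length >= lst_smooth_mb * 1e6, , drop = FALSE]
  lst <- 0L
  if (nrow(sm) > 0) {
    sm <- merge_cn_segments(sm)
    big <- sm$length >= lst_flank_mb * 1e6
    same_chrom <- sm$chrom[-1] == sm$chrom[-nrow(sm)]
    if (nrow(sm) > 1) {
      lst <- sum(same_chrom & big[-1] & big[-nrow(sm)])
    }
  }

  cen <- genome$chromosomes[, c("chrom", "cen_start", "cen_end", "length")]
  names(cen)[4] <- "chrom_len"
  mg <- dplyr::left_join(merged, cen, by = "chrom")
  imbalance <- mg$minor_cn != (mg$total_cn - mg$minor_cn)
  at_telomere <- mg$start <= mg$chrom_min | mg$end >= mg$chrom_max
  crosses_cen <- !is.na(mg$cen_start) &
    mg$start < mg$cen_start & mg$end > mg$cen_end
  tai <- sum(imbalance & at_telomere & !crosses_cen &
               mg$length > tai_min_mb * 1e6, na.rm = TRUE)

  list(hrd_loh = as.integer(hrd_loh), lst = as.integer(lst),
       tai = as.integer(tai),
       hrd_sum = as.integer(hrd_loh + lst + tai))
}

#' Fraction of genome altered and fraction of subclonal copy number
#'
#' A segment is altered when its fitted total copy number differs from
#' the baseline (diploid 2 by default; the sample's doubled baseline 4
#' with `baseline = "ploidy"` in WGD samples). `fga` is the altered
#' length over the total autosomal segment length. A segment is
#' subclonal by its `clonality` column when the segments carry one (see
#' [assign_cn_states()]), otherwise when its continuous copy number
#' deviates from the nearest integer by more than `subclonal_delta`;
#' `subclonal_cn_fraction` is the subclonal-and-changed length over the
#' changed length (0 when nothing is changed), where "changed" is
#' always relative to the sample's own baseline (4 in genome-doubled
#' samples) so the share of subclonal changes is not diluted in WGD
#' genomes.
#'
#' @param segments Fitted segment tibble (`total_cn`, `continuous_cn`,
#'   optionally `clonality`).
#' @param wgd Whole-genome-doubling flag for the sample.
#' @param baseline `"diploid"` (default) or `"ploidy"`.
#' @param subclonal_delta Non-integrality threshold (default 0.25),
#'   used when no `clonality` column is present.
#' @return List `fga`, `subclonal_cn_fraction`.
#' @export
compute_cn_fractions <- function(segments, wgd = FALSE,
                                 baseline = c("diploid", "ploidy"),
                                 subclonal_delta = 0.25) {
  baseline <- match.arg(baseline)
  seg <- segments[!is_sex_chrom(segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0) return(list(fga = 0, subclonal_cn_fraction = 0))
  b <- if (baseline == "ploidy" && isTRUE(wgd)) 4 else 2
  altered <- seg$total_cn != b
  fga <- sum(seg$length[altered]) / sum(seg$length)
  subcl <- if ("clonality" %in% names(seg)) {
    seg$clonality == "subclonal"
  } else {
    abs(seg$continuous_cn - round(seg$continuous_cn)) > subclonal_delta
  }
  # the subclonal fraction is a share of CN *changes*, so its
  # denominator is always relative to the sample's own baseline (4 in
  # genome-doubled samples): under a diploid baseline a WGD genome is
  # altered nearly everywhere and the share would be diluted to the
  # genome-wide subclonal fraction
  b_ch <- if (isTRUE(wgd)) 4 else 2
  changed <- seg$total_cn != b_ch
  scf <- if (any(changed)) {
    sum(seg$length[changed & subcl]) / sum(seg$length[changed])
  } else {
    0
  }
  list(fga = fga, subclonal_cn_fraction = scf)
}

#' Arm-level LOH and deep-loss calls
#'
#' Per autosomal chromosome arm, LOH is called when segments with minor
#' copy number 0 cover at least `span_threshold` (default 80%, inclusive)
#' of the arm; a deep loss requires the same coverage with total copy
#' number 0.
#'
#' @param segments Fitted segment tibble.
#' @param genome A `genome_model`.
#' @param span_threshold Minimum covered arm fraction (default 0.80).
#' @return Tibble with one row per arm: `chrom`, `arm`, `loh_span`,
#'   `deep_span`, `arm_loh`, `arm_deep_loss`.
#' @export
call_arm_events <- function(segments, genome, span_threshold = 0.80) {
  arms <- genome$arms
  seg <- segments[!is_sex_chrom(segments$chrom), , drop = FALSE]
  span_of <- function(sub, a) {
    s <- sub[sub$chrom == a$chrom, , drop = FALSE]
    if (nrow(s) == 0) return(0)
    ov <- pmax(0, pmin(s$end, a$end) - pmax(s$start, a$start) + 1)
    sum(ov) / a$length
  }
  loh_seg <- seg[seg$minor_cn == 0, , drop = FALSE]
  deep_seg <- seg[seg$total_cn == 0, , drop = FALSE]
  out <- arms
  out$loh_span <- vapply(seq_len(nrow(arms)), function(i)
    span_of(loh_seg, arms[i, ]), numeric(1))
  out$deep_span <- vapply(seq_len(nrow(arms)), function(i)
    span_of(deep_seg, arms[i, ]), numeric(1))
  out$arm_loh <- out$loh_span >= span_threshold
  out$arm_deep_loss <- out$deep_span >= span_threshold
  tibble::as_tibble(out)
}

#' Gene-level amplification and deletion calls
#'
#' The sample's predominant copy number is the length-weighted modal
#' integer total copy number of the autosomal segments. Each gene takes
#' the total copy number of the segment covering its midpoint; a gain of
#' two or more copies over the predominant state is an amplification and
#' a loss of two or more a deletion.
#'
#' @param segments Fitted segment tibble.
#' @param genes Gene interval tibble (`chrom`, `start`, `end`, `gene`,
#'   1-based inclusive; see [read_gene_bed()]).
#' @return Tibble `gene`, `gene_cn`, `predominant_cn`, `call`
#'   (amplification/deletion/neutral); genes outside all segments are
#'   skipped with a warning.
#' @export
call_gene_cnv <- function(segments, genes) {
  seg <- segments[!is_sex_chrom(segments$chrom), , drop = FALSE]
  wt <- tapply(seg$length, seg$total_cn, sum)
  predominant <- as.integer(names(wt)[which.max(wt)])
  mid <- floor((genes$start + genes$end) / 2)
  g <- dplyr::mutate(genes, mid = mid)
  hit <- dplyr::left_join(
    g, dplyr::select(seg, "chrom", seg_start = "start", seg_end = "end",
                     "total_cn"),
    by = dplyr::join_by("chrom", dplyr::between("mid", "seg_start", "seg_end"))
  )
  missing <- is.na(hit$total_cn)
  if (any(missing)) {
    warn(paste0("gene(s) outside all segments skipped: ",
                paste(hit$gene[missing], collapse = ", ")))
  }
  hit <- hit[!missing, , drop = FALSE]
  tibble::tibble(
    gene = hit$gene,
    gene_cn = hit$total_cn,
    predominant_cn = predominant,
    call = dplyr::case_when(
      hit$total_cn - predominant >= 2 ~ "amplification",
      predominant - hit$total_cn >= 2 ~ "deletion",
      TRUE ~ "neutral"))
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention (`start + 1`, `end` unchanged).
#'
#' @param path Path to a BED file (chrom, start, end, name).
#' @return Tibble `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene"),
                         show_col_types = FALSE, progress = FALSE,
                         comment = "#")
  tibble::tibble(chrom = bed$chrom, start = bed$start + 1,
                 end = bed$end, gene = bed$gene)
}
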