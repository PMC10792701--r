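#' Per-group simulation parameters
#'
#' Parameter block describing one patient group of a simulated cohort.
#' The package defaults mirror the study conditions the pipeline is built
#' for: a T790M-positive-like group with frequent whole-genome doubling,
#' higher mutational burden and subclonal load, and a clock-like-dominant
#' signature mixture, against a quieter negative-like group.
#'
#' @param wgd_prob Probability of whole-genome doubling (0-1).
#' @param tmb_mean Expected TMB in countable mutations per megabase.
#' @param tmb_sdlog Between-sample lognormal jitter on `tmb_mean`.
#' @param subclonal_mut_frac Fraction of mutations that are subclonal.
#' @param subclonal_cn_frac Fraction of altered segments made subclonal.
#' @param cn_alter_frac Fraction of segments deviating from the baseline
#'   copy-number state.
#' @param signature_weights Named weights over the reference signatures,
#'   summing to 1.
#' @param purity_range Uniform range for tumor purity.
#' @param depth_mean Mean sequencing depth (reads).
#' @param callable_mb Callable megabases.
#' @param n_segments Copy-number segments per genome.
#' @param ccf_subclonal_range Uniform range of subclonal cancer cell
#'   fractions.
#' @return A named list of validated parameters.
#' @export
group_sim_params <- function(wgd_prob = 0.5, tmb_mean = 2.5,
                             tmb_sdlog = 0.1,
                             subclonal_mut_frac = 0.5,
                             subclonal_cn_frac = 0.1,
                             cn_alter_frac = 0.25,
                             signature_weights = c(
                               SBS1 = 0.25, SBS5 = 0.20, SBS2 = 0.09,
                               SBS4 = 0.20, SBS13 = 0.07, SBS30 = 0.08,
                               SBS92 = 0.06, SBS96 = 0.05),
                             purity_range = c(0.3, 0.7),
                             depth_mean = 170, callable_mb = 35,
                             n_segments = 60,
                             ccf_subclonal_range = c(0.1, 0.6)) {
  p <- list(wgd_prob = wgd_prob, tmb_mean = tmb_mean, tmb_sdlog = tmb_sdlog,
            subclonal_mut_frac = subclonal_mut_frac,
            subclonal_cn_frac = subclonal_cn_frac,
            cn_alter_frac = cn_alter_frac,
            signature_weights = signature_weights,
            purity_range = purity_range, depth_mean = depth_mean,
            callable_mb = callable_mb, n_segments = n_segments,
            ccf_subclonal_range = ccf_subclonal_range)
  probs <- c(wgd_prob, subclonal_mut_frac, subclonal_cn_frac, cn_alter_frac)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (abs(sum(signature_weights) - 1) > 1e-6) {
    abort("signature_weights must sum to 1")
  }
  if (any(signature_weights < 0)) abort("signature_weights must be >= 0")
  if (tmb_mean <= 0 || depth_mean <= 0 || callable_mb <= 0 ||
      n_segments < 1) {
    abort("tmb_mean, depth_mean, callable_mb must be positive; n_segments >= 1")
  }
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 0 && r[2] <= 1
  if (!rng_ok(purity_range) || purity_range[1] <= 0 ||
      !rng_ok(ccf_subclonal_range)) {
    abort("purity_range and ccf_subclonal_range must be ranges within (0, 1]")
  }
  p
}

#' Two-group cohort simulation configuration
#'
#' Defaults encode the study conditions: 25 positive versus 14 negative
#' samples; WGD probability 0.80 vs 0.29; expected TMB 2.7 vs 2.2 mut/Mb;
#' subclonal mutation fraction 0.63 vs 0.55 (giving scTMB near 1.7 vs
#' 1.2); subclonal-CN fraction 0.16 vs 0.047; clock-like SBS1+5 weight
#' 0.53 vs 0.40; depth 170x; purity uniform on (0.3, 0.7); 35 callable
#' Mb; subclonal CCFs higher in the positive group (0.2-0.7 vs 0.1-0.4).
#'
#' @param n_pos,n_neg Group sizes.
#' @param seed Integer cohort seed; each sample draws from its own stream
#'   derived from `(seed, sample index)`.
#' @param pos,neg Group parameter blocks from [group_sim_params()].
#' @param logr_sd,baf_sd Gaussian noise on segment logR and BAF.
#' @param csq_props Named proportions of missense/synonymous/other
#'   consequences.
#' @param region_props Named proportions of exonic/splice/other regions.
#' @param pass_prob Probability a record carries the PASS filter.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(
    n_pos = 25, n_neg = 14, seed = 1,
    pos = group_sim_params(
      wgd_prob = 0.80, tmb_mean = 2.7, subclonal_mut_frac = 0.63,
      subclonal_cn_frac = 0.16,
      signature_weights = c(SBS1 = 0.30, SBS5 = 0.23, SBS2 = 0.08,
                            SBS4 = 0.15, SBS13 = 0.06, SBS30 = 0.08,
                            SBS92 = 0.06, SBS96 = 0.04),
      ccf_subclonal_range = c(0.2, 0.7)),
    neg = group_sim_params(
      wgd_prob = 0.29, tmb_mean = 2.2, subclonal_mut_frac = 0.55,
      subclonal_cn_frac = 0.047,
      signature_weights = c(SBS1 = 0.22, SBS5 = 0.18, SBS2 = 0.10,
                            SBS4 = 0.25, SBS13 = 0.08, SBS30 = 0.08,
                            SBS92 = 0.05, SBS96 = 0.04),
      ccf_subclonal_range = c(0.1, 0.4)),
    logr_sd = 0.05, baf_sd = 0.02,
    csq_props = c(missense = 0.60, synonymous = 0.25, other = 0.15),
    region_props = c(exonic = 0.95, splice = 0.04, other = 0.01),
    pass_prob = 0.98) {
  if (n_pos < 1 || n_neg < 1) abort("group sizes must be >= 1")
  if (logr_sd < 0 || baf_sd < 0) abort("noise sds must be >= 0")
  structure(list(n_pos = n_pos, n_neg = n_neg, seed = as.integer(seed),
                 pos = pos, neg = neg, logr_sd = logr_sd, baf_sd = baf_sd,
                 csq_props = csq_props / sum(csq_props),
                 region_props = region_props / sum(region_props),
                 pass_prob = pass_prob),
            class = "cohort_sim_config")
}

# Copy-number alteration states drawn for altered segments, relative to
# the (baseline total, baseline minor) of the sample.
alt_cn_states <- function(wgd) {
  if (wgd) {
    list(c = c(3, 5, 2, 4, 6), m = c(1, 2, 1, 0, 3),
         prob = c(0.35, 0.25, 0.20, 0.15, 0.05))
  } else {
    list(c = c(1, 3, 2, 4, 0), m = c(0, 1, 0, 2, 0),
         prob = c(0.30, 0.40, 0.15, 0.10, 0.05))
  }
}

#' Simulate allele-specific copy-number segments for one sample
#'
#' Segments tile every autosome of the genome model. Each segment keeps
#' the baseline state (2,1), or (4,2) under WGD, with probability
#' `1 - cn_alter_frac`, otherwise draws an altered integer state. A
#' fraction `subclonal_cn_frac` of altered segments is made subclonal by
#' mixing the baseline with a one-copy gain or loss at a mixing fraction
#' uniform on (0.55, 0.70), giving a non-integer average copy number
#' whose deviation from the nearest integer exceeds the 0.25 detection
#' threshold. Observed values are
#' `logR = log2((p*c + 2(1-p)) / (p*psi + 2(1-p)))` and
#' `BAF = (p*m + (1-p)) / (p*c + 2(1-p))` plus Gaussian noise, with `psi`
#' the length-weighted mean true copy number.
#'
#' @param params Group parameter block ([group_sim_params()]).
#' @param genome A `genome_model`.
#' @param purity True (and histopathological) tumor purity.
#' @param wgd Logical, simulate a genome-doubled sample.
#' @param logr_sd,baf_sd Observation noise.
#' @return List `segments` (chrom, start, end, length, logR, BAF) and
#'   `truth` (adds true_total_cn, true_minor_cn, true_clonality, and the
#'   sample ploidy as attribute `ploidy`).
#' @export
simulate_sample_segments <- function(params, genome, purity, wgd,
                                     logr_sd = 0.05, baf_sd = 0.02) {
  auto <- autosomes(genome)
  n_seg <- max(params$n_segments, nrow(auto))
  # allocate segments per chromosome proportional to length, >= 1 each
  alloc <- pmax(1, round(n_seg * auto$length / sum(auto$length)))
  seg <- purrr::map2_dfr(seq_len(nrow(auto)), alloc, function(i, k) {
    len <- auto$length[i]
    cuts <- if (k > 1) sort(sample.int(len - 1, k - 1)) else integer(0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, len)
    tibble::tibble(chrom = auto$chrom[i], start = starts, end = ends)
  })
  seg$length <- seg$end - seg$start + 1
  n <- nrow(seg)

  b_c <- if (wgd) 4 else 2
  b_m <- if (wgd) 2 else 1
  altered <- runif(n) < params$cn_alter_frac
  states <- alt_cn_states(wgd)
  pick <- sample.int(length(states$c), n, replace = TRUE, prob = states$prob)
  c_true <- ifelse(altered, states$c[pick], b_c)
  m_true <- ifelse(altered, states$m[pick], b_m)

  subclonal <- altered & runif(n) < params$subclonal_cn_frac
  f <- runif(n, 0.55, 0.70)
  gain <- runif(n) < 0.5
  c_sub <- b_c + ifelse(gain, 1, -1)
  m_sub <- pmin(b_m, floor(c_sub / 2))
  c_true <- ifelse(subclonal, b_c + f * (c_sub - b_c), c_true)
  m_true <- ifelse(subclonal, b_m + f * (m_sub - b_m), m_true)

  psi <- weighted.mean(c_true, seg$length)
  seg$logR <- expected_logr(purity, c_true, psi) + rnorm(n, 0, logr_sd)
  seg$BAF <- pmin(pmax(
    expected_baf(purity, c_true, m_true) + rnorm(n, 0, baf_sd), 0), 1)

  truth <- dplyr::mutate(seg,
                         true_total_cn = c_true, true_minor_cn = m_true,
                         true_clonality = ifelse(subclonal, "subclonal",
                                                 "clonal"))
  attr(truth, "ploidy") <- psi
  list(segments = seg, truth = truth)
}

#' Simulate somatic SNVs for one sample
#'
#' The mutation count is Poisson with mean
#' `tmb * callable_mb / P(countable)` so that the expected TMB
#' (missense + synonymous per Mb) matches the group's `tmb_mean` after
#' lognormal between-sample jitter. Mutations land uniformly on
#' length-weighted segments; clonal mutations have CCF 1 (and carry all
#' retained copies on LOH segments), subclonal ones draw CCF from the
#' configured range at multiplicity 1. Read support is
#' `Binomial(depth ~ Poisson(depth_mean), CCF * mult * p / (c*p + 2(1-p)))`.
#' Trinucleotide contexts are drawn from the sample's signature mixture;
#' half the records are emitted on the purine strand to exercise the
#' channel folding.
#'
#' @param params Group parameter block.
#' @param signatures A `signature_matrix`.
#' @param seg_truth Segment truth tibble from
#'   [simulate_sample_segments()].
#' @param purity True tumor purity.
#' @param csq_props,region_props,pass_prob Record annotation proportions
#'   (see [cohort_sim_config()]).
#' @return List `variants` (VCF-shaped tibble) and `truth` (adds
#'   true_ccf, true_clonality, true_multiplicity, expected_vaf).
#' @export
simulate_sample_mutations <- function(params, signatures, seg_truth, purity,
                                      csq_props = c(missense = 0.6,
                                                    synonymous = 0.25,
                                                    other = 0.15),
                                      region_props = c(exonic = 0.95,
                                                       splice = 0.04,
                                                       other = 0.01),
                                      pass_prob = 0.98) {
  countable <- sum(csq_props[c("missense", "synonymous")])
  tmb_s <- params$tmb_mean * rlnorm(1, 0, params$tmb_sdlog)
  n <- rpois(1, tmb_s * params$callable_mb / countable)
  if (n == 0) {
    empty <- tibble::tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), depth = integer(), alt_count = integer(),
      vaf = double(), filter_status = character(),
      consequence_class = character(), region = character(),
      trinucleotide_context = character())
    return(list(variants = empty,
                truth = dplyr::mutate(empty, true_ccf = double(),
                                      true_clonality = character(),
                                      true_multiplicity = double(),
                                      expected_vaf = double())))
  }
  si <- sample.int(nrow(seg_truth), n, replace = TRUE,
                   prob = seg_truth$length)
  pos <- seg_truth$start[si] +
    floor(runif(n) * (seg_truth$end[si] - seg_truth$start[si] + 1))
  c_loc <- seg_truth$true_total_cn[si]
  m_loc <- seg_truth$true_minor_cn[si]

  subclonal <- runif(n) < params$subclonal_mut_frac
  ccf <- ifelse(subclonal,
                runif(n, params$ccf_subclonal_range[1],
                      params$ccf_subclonal_range[2]), 1)
  loh <- round(m_loc) == 0
  mult <- ifelse(!subclonal & loh, pmax(round(c_loc), 1), 1)
  evaf <- pmin(pmax(ccf * mult * purity /
                      (c_loc * purity + 2 * (1 - purity)), 1e-9), 1)
  depth <- pmax(rpois(n, params$depth_mean), 1L)
  alt_count <- rbinom(n, depth, evaf)

  # contexts from the signature mixture
  w <- params$signature_weights[colnames(signatures)]
  if (anyNA(w)) abort("signature_weights must name columns of the reference")
  chan_p <- as.vector(unclass(signatures) %*% w)
  chan <- sample(sbs96_channels(), n, replace = TRUE, prob = chan_p)
  ref <- substr(chan, 3, 3)
  alt <- substr(chan, 5, 5)
  ctx <- paste0(substr(chan, 1, 1), ref, substr(chan, 7, 7))
  flip <- runif(n) < 0.5
  ref[flip] <- comp_base(ref[flip])
  alt[flip] <- comp_base(alt[flip])
  ctx[flip] <- revcomp(ctx[flip])

  truth <- tibble::tibble(
    chrom = seg_truth$chrom[si], pos = as.integer(pos),
    ref = ref, alt = alt,
    depth = as.integer(depth), alt_count = as.integer(alt_count),
    vaf = alt_count / depth,
    filter_status = ifelse(runif(n) < pass_prob, "PASS", "lowq"),
    consequence_class = sample(names(csq_props), n, replace = TRUE,
                               prob = csq_props),
    region = sample(names(region_props), n, replace = TRUE,
                    prob = region_props),
    trinucleotide_context = ctx,
    true_ccf = ccf,
    true_clonality = ifelse(subclonal, "subclonal", "clonal"),
    true_multiplicity = mult,
    expected_vaf = evaf)
  truth <- dplyr::arrange(truth, .data$chrom, .data$pos)
  variants <- dplyr::select(truth, -dplyr::starts_with("true_"),
                            -"expected_vaf")
  list(variants = variants, truth = truth)
}

#' Simulate a two-group cohort
#'
#' Draws every sample from its own pseudo-random stream derived from
#' `(seed, sample index)`, so cohorts are fully reproducible and samples
#' are reproducible independently. Positive-group samples are labelled
#' `T790Mpos`, negative `T790Mneg`; the histopathological purity reported
#' in the metadata equals the true simulated purity.
#'
#' @param config A [cohort_sim_config()].
#' @param genome A `genome_model` (default: bundled hg19-like autosomes).
#' @param signatures A `signature_matrix` (default: bundled synthetic
#'   reference).
#' @param dir Optional output directory; when given, per-sample VCFs and
#'   segment TSVs plus the cohort metadata TSV are written via
#'   [write_cohort()].
#' @return A `cohort_sim` list: `samples` (named list with `variants` and
#'   `segments` tibbles per sample), `metadata`, and `truth` (`samples`,
#'   `variants`, `segments`, `signature_weights` tibbles).
#' @export
simulate_cohort <- function(config = cohort_sim_config(),
                            genome = hetpanel_genome(),
                            signatures = hetpanel_signatures(),
                            dir = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_pos + config$n_neg
  ids <- c(sprintf("POS%02d", seq_len(config$n_pos)),
           sprintf("NEG%02d", seq_len(config$n_neg)))
  groups <- c(rep("T790Mpos", config$n_pos), rep("T790Mneg", config$n_neg))

  samples <- list()
  meta <- vector("list", n)
  truth_samples <- vector("list", n)
  truth_variants <- vector("list", n)
  truth_segments <- vector("list", n)
  truth_sigw <- vector("list", n)

  for (i in seq_len(n)) {
    params <- if (groups[i] == "T790Mpos") config$pos else config$neg
    set.seed((config$seed %% 20000L) * 100000L + i)
    purity <- runif(1, params$purity_range[1], params$purity_range[2])
    wgd <- runif(1) < params$wgd_prob
    segs <- simulate_sample_segments(params, genome, purity, wgd,
                                     logr_sd = config$logr_sd,
                                     baf_sd = config$baf_sd)
    muts <- simulate_sample_mutations(params, signatures, segs$truth, purity,
                                      csq_props = config$csq_props,
                                      region_props = config$region_props,
                                      pass_prob = config$pass_prob)
    samples[[ids[i]]] <- list(variants = muts$variants,
                              segments = segs$segments)
    meta[[i]] <- tibble::tibble(sample = ids[i], group = groups[i],
                                purity = purity,
                                callable_mb = params$callable_mb)
    truth_samples[[i]] <- tibble::tibble(
      sample = ids[i], group = groups[i], purity = purity,
      ploidy = attr(segs$truth, "ploidy"), wgd = wgd)
    truth_variants[[i]] <- dplyr::mutate(muts$truth, sample = ids[i],
                                         .before = 1)
    truth_segments[[i]] <- dplyr::mutate(segs$truth, sample = ids[i],
                                         .before = 1)
    truth_sigw[[i]] <- tibble::tibble(
      sample = ids[i], signature = names(params$signature_weights),
      weight = unname(params$signature_weights))
  }

  structure(list(
    samples = samples,
    metadata = dplyr::bind_rows(meta),
    truth = list(samples = dplyr::bind_rows(truth_samples),
                 variants = dplyr::bind_rows(truth_variants),
                 segments = dplyr::bind_rows(truth_segments),
                 signature_weights = dplyr::bind_rows(truth_sigw)),
    config = config),
    class = "cohort_sim") -> sim
  if (!is.null(dir)) write_cohort(sim, dir)
  sim
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d samples (%d pos / %d neg), seed %d\n",
              nrow(x$metadata), x$config$n_pos, x$config$n_neg,
              x$config$seed))
  invisible(x)
}

#' Write a simulated cohort to standard-format files
#'
#' Emits one VCF 4.2 and one segment TSV per sample plus
#' `cohort_metadata.tsv`.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(sim$samples)) {
    write_somatic_vcf(sim$samples[[id]]$variants,
                      file.path(dir, paste0(id, ".vcf")), sample_id = id)
    write_segments_table(sim$samples[[id]]$segments,
                         file.path(dir, paste0(id, "_segments.tsv")))
  }
  readr::write_tsv(sim$metadata, file.path(dir, "cohort_metadata.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory with `cohort_metadata.tsv` and per-sample files.
#' @return List `samples` (variants/segments per sample) and `metadata`.
#' @export
read_cohort <- function(dir) {
  meta <- read_cohort_metadata(file.path(dir, "cohort_metadata.tsv"))
  missing <- meta$sample[!file.exists(file.path(dir, paste0(meta$sample,
                                                            ".vcf")))]
  if (length(missing)) {
    abort(paste0("metadata lists samples without files: ",
                 paste(missing, collapse = ", ")))
  }
  samples <- lapply(meta$sample, function(id) {
    list(variants = read_somatic_vcf(file.path(dir, paste0(id, ".vcf"))),
         segments = read_segments_table(
           file.path(dir, paste0(id, "_segments.tsv"))))
  })
  names(samples) <- meta$sample
  list(samples = samples, metadata = meta)
}

#' Load a simulation configuration from YAML
#'
#' The YAML mirrors [cohort_sim_config()]: top-level `n_pos`, `n_neg`,
#' `seed`, `logr_sd`, `baf_sd`, and `pos`/`neg` blocks with
#' [group_sim_params()] fields (`signature_weights` as a named map).
#'
#' @param path Path to the YAML file.
#' @return A `cohort_sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_group <- function(block) {
    if (is.null(block)) return(NULL)
    if (!is.null(block$signature_weights)) {
      block$signature_weights <- unlist(block$signature_weights)
    }
    for (k in c("purity_range", "ccf_subclonal_range")) {
      if (!is.null(block[[k]])) block[[k]] <- as.numeric(block[[k]])
    }
    do.call(group_sim_params, block)
  }
  args <- y[intersect(names(y), c("n_pos", "n_neg", "seed", "logr_sd",
                                  "baf_sd", "pass_prob"))]
  if (!is.null(y$pos)) args$pos <- as_group(y$pos)
  if (!is.null(y$neg)) args$neg <- as_group(y$neg)
  if (!is.null(y$csq_props)) args$csq_props <- unlist(y$csq_props)
  if (!is.null(y$region_props)) args$region_props <- unlist(y$region_props)
  do.call(cohort_sim_config, args)
}
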