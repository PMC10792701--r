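#' Build a 96-channel mutation spectrum
#'
#' Counts single-base substitutions into the canonical pyrimidine-centric
#' channels of [sbs96_channels()], reverse-complementing purine-reference
#' calls. Indels, MNVs and SNVs with missing or malformed trinucleotide
#' context are excluded; their number is reported via a message and the
#' `n_excluded` attribute.
#'
#' @param variants Variant tibble with `ref`, `alt` and
#'   `trinucleotide_context`.
#' @return Tibble `channel`, `count` (96 rows, canonical order) with
#'   attributes `total_snvs` and `n_excluded`.
#' @export
build_mutation_spectrum <- function(variants) {
  canon <- sbs96_channels()
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  ch <- rep(NA_character_, nrow(variants))
  if (any(is_snv)) {
    ch[is_snv] <- sbs96_channel(variants$ref[is_snv], variants$alt[is_snv],
                                variants$trinucleotide_context[is_snv])
  }
  n_excl <- sum(is.na(ch))
  if (n_excl > 0) {
    inform(sprintf(
      "%d variant(s) excluded from the spectrum (non-SNV or unusable context)",
      n_excl))
  }
  counts <- table(factor(ch, levels = canon))
  out <- tibble::tibble(channel = canon, count = as.integer(counts))
  attr(out, "total_snvs") <- sum(out$count)
  attr(out, "n_excluded") <- n_excl
  out
}

#' Refit reference signature weights by non-negative least squares
#'
#' Decomposes a normalized 96-channel spectrum over the columns of a
#' signature reference matrix by deterministic NNLS (Lawson-Hanson active
#' set, via `pracma::lsqnonneg`) and renormalizes the weights to sum 1.
#' The clock-like share is reported as `100 * (w_SBS1 + w_SBS5)` percent
#' when those columns are present.
#'
#' @param spectrum Spectrum tibble from [build_mutation_spectrum()] (or
#'   any tibble with `channel`, `count`).
#' @param signatures A `signature_matrix`.
#' @param min_snvs Minimum SNV count for a fit (default 20); below it all
#'   weights are `NA`.
#' @return Named list: `weights` (named vector summing to 1),
#'   `clocklike_sbs1_5` (percent), `residual` (L2 norm of the fit
#'   residual on the normalized spectrum), `total_snvs`.
#' @export
fit_signature_weights <- function(spectrum, signatures, min_snvs = 20) {
  canon <- sbs96_channels()
  if (!all(canon %in% spectrum$channel)) {
    abort("spectrum must cover all 96 canonical channels")
  }
  counts <- spectrum$count[match(canon, spectrum$channel)]
  total <- sum(counts)
  signames <- colnames(signatures)
  if (total < min_snvs) {
    return(list(weights = setNames(rep(NA_real_, length(signames)), signames),
                clocklike_sbs1_5 = NA_real_,
                residual = NA_real_, total_snvs = total))
  }
  y <- counts / total
  fit <- pracma::lsqnonneg(unclass(signatures), y)
  w <- fit$x
  if (sum(w) == 0) {
    abort("signature fit degenerate: all weights zero")
  }
  w <- w / sum(w)
  names(w) <- signames
  resid <- sqrt(sum((y - unclass(signatures) %*% fit$x)^2))
  clock <- if (all(c("SBS1", "SBS5") %in% signames)) {
    100 * (w[["SBS1"]] + w[["SBS5"]])
  } else {
    NA_real_
  }
  list(weights = w, clocklike_sbs1_5 = clock, residual = resid,
       total_snvs = total)
}
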