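#' Tumor mutational burden
#'
#' TMB is the count of missense plus synonymous variants divided by the
#' callable target size in megabases. With `subset = "subclonal"` only
#' variants already classified subclonal are counted (scTMB); other
#' consequence classes never enter the numerator.
#'
#' @param variants Filtered variant tibble with `consequence_class` and,
#'   for the subclonal subset, `clonality`.
#' @param callable_mb Callable megabases (> 0).
#' @param subset `"all"` or `"subclonal"`.
#' @return Mutations per megabase (double).
#' @examples
#' v <- tibble::tibble(
#'   consequence_class = c(rep("missense", 4), rep("synonymous", 2), "other"))
#' compute_tmb(v, 30)  # (4 + 2) / 30 = 0.2
#' @export
compute_tmb <- function(variants, callable_mb, subset = c("all", "subclonal")) {
  subset <- match.arg(subset)
  if (!is.numeric(callable_mb) || length(callable_mb) != 1 ||
      is.na(callable_mb) || callable_mb <= 0) {
    abort("callable_mb must be a single positive number")
  }
  keep <- variants$consequence_class %in% c("missense", "synonymous")
  if (subset == "subclonal") {
    if (!"clonality" %in% names(variants)) {
      abort("subset = \"subclonal\" requires a clonality column")
    }
    keep <- keep & !is.na(variants$clonality) &
      variants$clonality == "subclonal"
  }
  sum(keep) / callable_mb
}

#' Binomial clonality classification of somatic variants
#'
#' For each variant the expected clonal VAF is
#' `v* = m * p / (CN * p + 2 * (1 - p))` with mutant multiplicity `m = 1`
#' when the minor allele is retained and `m = CN` under LOH (all retained
#' copies mutated). The one-sided p-value is the lower binomial tail
#' `P(X <= alt_count | depth, v*)`; a variant is subclonal when
#' `p-value < alpha`, clonal otherwise. Variants whose alt count meets or
#' exceeds the clonal expectation therefore always classify clonal.
#'
#' @param variants Variant tibble with `depth`, `alt_count`,
#'   `local_total_cn`, `local_minor_cn`.
#' @param purity Histopathological tumor purity `p` in (0, 1].
#' @param alpha Significance level of the subclonality call (default 0.05).
#' @return `variants` with `clonality_p` and
#'   `clonality` (`"clonal"`/`"subclonal"`) columns.
#' @export
classify_clonality <- function(variants, purity, alpha = 0.05) {
  if (!length(purity) == 1 || is.na(purity) || purity <= 0 || purity > 1) {
    abort("purity must be a single value in (0, 1]")
  }
  if (nrow(variants) == 0) {
    return(dplyr::mutate(variants, clonality_p = double(),
                         clonality = character()))
  }
  if (any(variants$depth <= 0)) {
    abort("variant with zero depth cannot be classified")
  }
  cn <- variants$local_total_cn
  m <- ifelse(variants$local_minor_cn > 0, 1, cn)
  v_star <- m * purity / (cn * purity + 2 * (1 - purity))
  v_star <- pmin(pmax(v_star, 1e-9), 1 - 1e-9)
  pval <- pbinom(variants$alt_count, variants$depth, v_star)
  dplyr::mutate(variants,
                clonality_p = pval,
                clonality = ifelse(pval < alpha, "subclonal", "clonal"))
}

#' MATH score: mutant-allele tumor heterogeneity
#'
#' The ratio of the scaled median absolute deviation of the variant
#' allele frequencies to their median,
#' `1.4826 * median(|vaf - median(vaf)|) / median(vaf)`, reported as a
#' plain ratio (not x100).
#'
#' @param vafs Numeric vector of VAF fractions.
#' @param min_variants Minimum number of VAFs required (default 3); below
#'   it the score is undefined and `NA` is returned.
#' @return MATH ratio, or `NA_real_` when undefined.
#' @examples
#' compute_math(c(0.2, 0.3, 0.4))  # 1.4826 * 0.1 / 0.3 = 0.4942
#' @export
compute_math <- function(vafs, min_variants = 3) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_variants) return(NA_real_)
  med <- median(vafs)
  if (med == 0) abort("median VAF is zero; MATH undefined")
  mad(vafs, constant = 1.4826) / med
}

#' Tumor-adjusted variant allele frequency (TVAF)
#'
#' Normalizes each VAF for tumor purity and local copy-number state so
#' that clonal mutations map to 50%. The effective purity is
#' `q = CN * p / (CN * p + 2 * (1 - p))` (equal to `p` at CN 2) and the
#' LOH factor `h` is 0.5 when heterozygosity is lost and 1 otherwise.
#' The default orientation divides by `q`
#' (`TVAF = 100 * h * vaf / q`, capped at 100), which fulfils the
#' purpose of subtracting purity and LOH effects; the literal product
#' reading `100 * h * q * vaf` is available as `mode = "product"` for
#' sensitivity analysis.
#'
#' @param vaf VAF fraction(s).
#' @param purity Histopathological purity `p` in (0, 1].
#' @param cn Local total copy number (>= 0).
#' @param loh_flag Logical, local minor copy number is zero.
#' @param mode `"ratio"` (default) or `"product"`.
#' @return TVAF in percent; `NA` where the variant must be excluded
#'   (CN 0 makes `q` zero).
#' @examples
#' compute_tvaf(0.25, purity = 0.5, cn = 2, loh_flag = FALSE)  # 50
#' compute_tvaf(0.50, purity = 0.5, cn = 2, loh_flag = TRUE)   # 50
#' @export
compute_tvaf <- function(vaf, purity, cn, loh_flag,
                         mode = c("ratio", "product")) {
  mode <- match.arg(mode)
  if (any(purity <= 0 | purity > 1)) {
    abort("purity must lie in (0, 1]")
  }
  q <- cn * purity / (cn * purity + 2 * (1 - purity))
  h <- ifelse(loh_flag, 0.5, 1)
  bad <- q <= 0
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf("%d variant(s) with zero effective purity excluded from TVAF",
                 sum(bad, na.rm = TRUE)))
  }
  tv <- switch(mode,
               ratio = 100 * h * vaf / q,
               product = 100 * h * q * vaf)
  tv[bad] <- NA_real_
  pmin(tv, 100)
}

#' Median TVAF of a sample
#'
#' @param variants Filtered variant tibble with `vaf`, `local_total_cn`,
#'   `loh_flag`.
#' @param purity Histopathological purity.
#' @param mode Passed to [compute_tvaf()].
#' @return Median TVAF in percent (`NA` when no usable variants).
#' @export
compute_median_tvaf <- function(variants, purity, mode = "ratio") {
  if (nrow(variants) == 0) return(NA_real_)
  tv <- compute_tvaf(variants$vaf, purity, variants$local_total_cn,
                     variants$loh_flag, mode = mode)
  if (all(is.na(tv))) return(NA_real_)
  median(tv, na.rm = TRUE)
}
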