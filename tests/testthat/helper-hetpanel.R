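# Shared fixtures and independent oracles for the test suite.

# four 100 Mb autosomes with a 40-42 Mb centromere, plus a sex chromosome
mini_genome <- function(with_sex = FALSE) {
  tab <- tibble::tibble(
    chrom = paste0("chr", 1:4),
    length = 1e8, cen_start = 4e7, cen_end = 4.2e7)
  if (with_sex) {
    tab <- dplyr::bind_rows(tab, tibble::tibble(
      chrom = "chrX", length = 1e8, cen_start = 4e7, cen_end = 4.2e7))
  }
  new_genome_model(tab)
}

# segment constructor: seg("chr1", 1, 10e6, c = 2, m = 1)
seg_row <- function(chrom, start, end, c = 2, m = 1, cont = NULL) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 length = end - start + 1, total_cn = c, minor_cn = m,
                 continuous_cn = if (is.null(cont)) c else cont)
}

# tile one chromosome with alternating states given as list of
# c(start, end, total, minor)
make_segments <- function(...) {
  dplyr::bind_rows(...)
}

toy_variants <- function(n = 6, vaf = 0.25, depth = 150,
                         csq = "missense") {
  n_alt <- as.integer(round(vaf * depth))
  n_dp <- as.integer(depth)
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n) * 1000L, ref = "C", alt = "T",
    depth = n_dp, alt_count = n_alt,
    vaf = n_alt / n_dp, filter_status = "PASS",
    consequence_class = rep_len(csq, n), region = "exonic",
    trinucleotide_context = "ACA")
}

# ---- independent oracles -------------------------------------------------

# MATH by explicit sorting-based median / absolute deviations
oracle_math <- function(v) {
  med <- function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  m <- med(v)
  1.4826 * med(abs(v - m)) / m
}

# AUC by brute-force pair counting with half-ties
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(pos) * length(neg))
}

# BH by explicit sort / step-up / cumulative minimum
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# two-sided Wilcoxon rank-sum p by full enumeration of group assignments
oracle_wilcoxon_perm <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(all_v)[seq_len(n1)])
  combs <- utils::combn(length(all_v), n1)
  rk <- rank(all_v)
  stats <- apply(combs, 2, function(idx) sum(rk[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-9)
}

# write a small VCF string to a temp file
write_vcf_lines <- function(records,
                            header_extra = character()) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"csq\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"region\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"context\">",
    "##FILTER=<ID=lowq,Description=\"low quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"allele depths\">",
    header_extra,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(hdr, records), path)
  path
}
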