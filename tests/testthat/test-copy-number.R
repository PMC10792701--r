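test_that("expected BAF and logR follow the purity mixture model", {
  # p = 0.5, c = 1, m = 0: (0 + 0.5) / (0.5 + 1.0) = 1/3
  expect_equal(expected_baf(0.5, 1, 0), 1 / 3)
  expect_equal(expected_baf(0.5, 2, 1), 0.5)
  expect_equal(expected_logr(0.6, 2, 2), 0)
  # WGD sample relative to its own ploidy
  expect_equal(expected_logr(0.5, 4, 4), 0)
})

test_that("purity/ploidy fitting recovers clonal noiseless simulations exactly", {
  g <- mini_genome()
  params <- group_sim_params(subclonal_cn_frac = 0, n_segments = 30)
  set.seed(21)
  for (case in list(c(0.6, FALSE), c(0.5, TRUE), c(0.35, FALSE))) {
    s <- simulate_sample_segments(params, g, case[1], as.logical(case[2]),
                                  logr_sd = 0, baf_sd = 0)
    fit <- suppressWarnings(fit_purity_ploidy(s$segments,
                                              purity_histo = case[1]))
    expect_equal(fit$solution$purity, case[1], tolerance = 0.011)
    expect_equal(fit$solution$ploidy, attr(s$truth, "ploidy"),
                 tolerance = 0.1)
    # fitted states match the simulated truth
    expect_equal(fit$segments$total_cn, s$truth$true_total_cn)
    expect_equal(fit$segments$minor_cn, s$truth$true_minor_cn)
  }
  expect_error(fit_purity_ploidy(
    tibble::tibble(chrom = character(), start = numeric(),
                   end = numeric(), logR = numeric(), BAF = numeric()),
    0.5), "no autosomal segments")
})

test_that("ploidy is the length-weighted mean and WGD threshold is inclusive", {
  all2 <- seg_row("chr1", 1, 1e8, c = 2, m = 1)
  expect_equal(compute_ploidy_and_wgd(all2), list(ploidy = 2, wgd = FALSE))
  all4 <- seg_row("chr1", 1, 1e8, c = 4, m = 2)
  expect_equal(compute_ploidy_and_wgd(all4), list(ploidy = 4, wgd = TRUE))
  half <- make_segments(seg_row("chr1", 1, 5e7, c = 2),
                        seg_row("chr1", 5e7 + 1, 1e8, c = 4, m = 2))
  pw <- compute_ploidy_and_wgd(half)
  expect_equal(pw$ploidy, 3.0)
  expect_true(pw$wgd)  # boundary inclusive
  # sex chromosomes excluded
  with_x <- dplyr::bind_rows(all2, seg_row("chrX", 1, 1e8, c = 8, m = 4))
  expect_equal(compute_ploidy_and_wgd(with_x)$ploidy, 2)
})

# ---- HRD scar fixtures, hand-counted -------------------------------------

hrd_of <- function(segments) {
  unlist(compute_hrd_scores(segments, mini_genome()))
}

diploid_chrom <- function(chrom) seg_row(chrom, 1, 1e8, c = 2, m = 1)

test_that("HRD components match hand counts on constructed layouts", {
  # 1. fully diploid balanced genome
  expect_equal(hrd_of(dplyr::bind_rows(lapply(paste0("chr", 1:4),
                                              diploid_chrom))),
               c(hrd_loh = 0, lst = 0, tai = 0, hrd_sum = 0))

  # 2. whole-chromosome LOH is excluded from HRD-LOH; it crosses the
  #    centromere so it is no TAI either, and merging leaves no breakpoint
  whole <- make_segments(seg_row("chr1", 1, 6e7, c = 2, m = 0),
                         seg_row("chr1", 6e7 + 1, 1e8, c = 2, m = 0))
  expect_equal(hrd_of(whole), c(hrd_loh = 0, lst = 0, tai = 0, hrd_sum = 0))

  # 3. 20 Mb interstitial LOH: one HRD-LOH; two breakpoints with all
  #    flanks >= 10 Mb
  inter <- make_segments(seg_row("chr1", 1, 1e7),
                         seg_row("chr1", 1e7 + 1, 3e7, c = 2, m = 0),
                         seg_row("chr1", 3e7 + 1, 1e8))
  expect_equal(hrd_of(inter), c(hrd_loh = 1, lst = 2, tai = 0, hrd_sum = 3))

  # 4. the 15 Mb HRD-LOH boundary is strict
  loh15 <- make_segments(seg_row("chr1", 1, 2e7),
                         seg_row("chr1", 2e7 + 1, 2e7 + 15e6, c = 2, m = 0),
                         seg_row("chr1", 2e7 + 15e6 + 1, 1e8))
  expect_equal(hrd_of(loh15)[["hrd_loh"]], 0)
  loh16 <- make_segments(seg_row("chr1", 1, 2e7),
                         seg_row("chr1", 2e7 + 1, 2e7 + 16e6, c = 2, m = 0),
                         seg_row("chr1", 2e7 + 16e6 + 1, 1e8))
  expect_equal(hrd_of(loh16)[["hrd_loh"]], 1)

  # 5. short telomeric LOH: TAI only (flank below the LST 10 Mb rule)
  telo <- make_segments(seg_row("chr1", 1, 8e6, c = 1, m = 0),
                        seg_row("chr1", 8e6 + 1, 1e8))
  expect_equal(hrd_of(telo), c(hrd_loh = 0, lst = 0, tai = 1, hrd_sum = 1))

  # 6. telomeric imbalance crossing the centromere is no TAI
  cross <- make_segments(seg_row("chr1", 1, 5e7, c = 3, m = 1),
                         seg_row("chr1", 5e7 + 1, 1e8))
  expect_equal(hrd_of(cross), c(hrd_loh = 0, lst = 1, tai = 0, hrd_sum = 1))

  # 7. sub-3 Mb fragments are smoothed away before LST counting
  blip <- make_segments(seg_row("chr1", 1, 5e7),
                        seg_row("chr1", 5e7 + 1, 5.2e7, c = 3, m = 1),
                        seg_row("chr1", 5.2e7 + 1, 1e8))
  expect_equal(hrd_of(blip), c(hrd_loh = 0, lst = 0, tai = 0, hrd_sum = 0))

  # 8. large-scale transition with a q-arm telomeric imbalance
  lst1 <- make_segments(seg_row("chr1", 1, 5e7),
                        seg_row("chr1", 5e7 + 1, 1e8, c = 3, m = 1))
  expect_equal(hrd_of(lst1), c(hrd_loh = 0, lst = 1, tai = 1, hrd_sum = 2))

  # 9. 9 Mb flank defeats LST; 91 Mb LOH counts (not whole chromosome)
  #    but crosses the centromere, so no TAI
  flank9 <- make_segments(seg_row("chr1", 1, 9e6),
                          seg_row("chr1", 9e6 + 1, 1e8, c = 1, m = 0))
  expect_equal(hrd_of(flank9), c(hrd_loh = 1, lst = 0, tai = 0, hrd_sum = 1))

  # 10. balanced genome-doubled genome carries no scars
  wgd <- dplyr::bind_rows(lapply(paste0("chr", 1:4), function(ch)
    seg_row(ch, 1, 1e8, c = 4, m = 2)))
  expect_equal(hrd_of(wgd), c(hrd_loh = 0, lst = 0, tai = 0, hrd_sum = 0))

  # 11. homozygous deletions are not LOH and balanced (0,0) is no TAI
  deep <- make_segments(seg_row("chr1", 1, 1e7),
                        seg_row("chr1", 1e7 + 1, 3e7, c = 0, m = 0),
                        seg_row("chr1", 3e7 + 1, 1e8))
  expect_equal(hrd_of(deep), c(hrd_loh = 0, lst = 2, tai = 0, hrd_sum = 2))

  # 12. adjacent same-state LOH segments merge before length gating
  merged <- make_segments(seg_row("chr1", 1, 2e7),
                          seg_row("chr1", 2e7 + 1, 3e7, c = 2, m = 0),
                          seg_row("chr1", 3e7 + 1, 3.9e7, c = 2, m = 0),
                          seg_row("chr1", 3.9e7 + 1, 1e8))
  expect_equal(hrd_of(merged)[["hrd_loh"]], 1)  # 19 Mb after merging

  # additivity across chromosomes
  combo <- dplyr::bind_rows(inter, dplyr::mutate(telo, chrom = "chr2"),
                            dplyr::mutate(lst1, chrom = "chr3"))
  h <- compute_hrd_scores(combo, mini_genome())
  expect_equal(h$hrd_loh, 1)
  expect_equal(h$lst, 3)   # 2 from the interstitial LOH, 1 from chr3
  expect_equal(h$tai, 2)   # chr2 telomeric LOH and the chr3 q arm

  expect_equal(h$hrd_sum, h$hrd_loh + h$lst + h$tai)
})

test_that("genome fractions use the declared baselines", {
  all2 <- dplyr::bind_rows(lapply(paste0("chr", 1:2), diploid_chrom))
  expect_equal(compute_cn_fractions(all2),
               list(fga = 0, subclonal_cn_fraction = 0))

  mix <- make_segments(seg_row("chr1", 1, 3e7, c = 3, m = 1, cont = 3),
                       seg_row("chr1", 3e7 + 1, 1e8, c = 2, m = 1, cont = 2))
  expect_equal(compute_cn_fractions(mix)$fga, 0.3)

  # 40 Mb altered of which a 20 Mb segment has continuous CN 2.5
  sub <- make_segments(
    seg_row("chr1", 1, 2e7, c = 3, m = 1, cont = 2.5),
    seg_row("chr1", 2e7 + 1, 4e7, c = 3, m = 1, cont = 3),
    seg_row("chr1", 4e7 + 1, 1e8, c = 2, m = 1, cont = 2))
  fr <- compute_cn_fractions(sub)
  expect_equal(fr$fga, 0.4)
  expect_equal(fr$subclonal_cn_fraction, 0.5)

  # a clonality column takes precedence over the delta rule
  sub2 <- dplyr::mutate(sub, clonality = c("clonal", "subclonal", "clonal"))
  expect_equal(compute_cn_fractions(sub2)$subclonal_cn_fraction, 0.5)

  # WGD: FGA baseline diploid by default, ploidy-relative behind the
  # option; the subclonal share is always relative to the doubled state
  wgd <- make_segments(
    seg_row("chr1", 1, 8e7, c = 4, m = 2, cont = 4),
    seg_row("chr1", 8e7 + 1, 1e8, c = 5, m = 2, cont = 4.6))
  expect_equal(compute_cn_fractions(wgd, wgd = TRUE)$fga, 1)
  expect_equal(compute_cn_fractions(wgd, wgd = TRUE,
                                    baseline = "ploidy")$fga, 0.2)
  expect_equal(compute_cn_fractions(wgd, wgd = TRUE)$subclonal_cn_fraction,
               1)  # the only changed segment (vs 4) is subclonal

  # invariance under splitting a segment into identical halves
  split <- dplyr::bind_rows(
    seg_row("chr1", 1, 1e7, c = 3, m = 1, cont = 2.5),
    seg_row("chr1", 1e7 + 1, 2e7, c = 3, m = 1, cont = 2.5),
    sub[-1, ])
  expect_equal(compute_cn_fractions(split), compute_cn_fractions(sub))
})

test_that("arm events require 80 percent span, inclusive", {
  g <- mini_genome()
  p_len <- g$arms$length[g$arms$chrom == "chr1" & g$arms$arm == "p"]
  span_seg <- function(frac, c = 2, m = 0) {
    cover <- ceiling(frac * p_len)  # smallest integer span reaching frac
    make_segments(seg_row("chr1", 1, cover, c = c, m = m),
                  seg_row("chr1", cover + 1, 1e8))
  }
  for (case in list(c(0.79, FALSE), c(0.80, TRUE), c(0.85, TRUE))) {
    ev <- call_arm_events(span_seg(case[1]), g)
    got <- ev$arm_loh[ev$chrom == "chr1" & ev$arm == "p"]
    expect_equal(got, as.logical(case[2]), info = paste("span", case[1]))
  }
  # deep loss requires total CN 0, not just LOH
  ev_loh <- call_arm_events(span_seg(0.85, c = 1, m = 0), g)
  expect_false(any(ev_loh$arm_deep_loss))
  ev_deep <- call_arm_events(span_seg(0.80, c = 0, m = 0), g)
  expect_true(ev_deep$arm_deep_loss[ev_deep$chrom == "chr1" &
                                      ev_deep$arm == "p"])
})

test_that("gene calls compare against the predominant copy number", {
  seg_dip <- make_segments(seg_row("chr1", 1, 6e7),
                           seg_row("chr1", 6e7 + 1, 9e7, c = 4, m = 2),
                           seg_row("chr1", 9e7 + 1, 1e8, c = 3, m = 1))
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(7e7, 9.5e7, 1e7, 2e8),
                          end = c(7.1e7, 9.6e7, 1.1e7, 2.1e8),
                          gene = c("AMP1", "ONE_UP", "NEUTRAL", "OUTSIDE"))
  expect_warning(calls <- call_gene_cnv(seg_dip, genes), "OUTSIDE")
  expect_equal(calls$predominant_cn, rep(2L, 3))
  expect_equal(calls$call[calls$gene == "AMP1"], "amplification")
  expect_equal(calls$call[calls$gene == "ONE_UP"], "neutral")

  # WGD genome: predominant 4, a diploid gene region is a deletion
  seg_wgd <- make_segments(seg_row("chr1", 1, 8e7, c = 4, m = 2),
                           seg_row("chr1", 8e7 + 1, 1e8, c = 2, m = 1))
  g2 <- tibble::tibble(chrom = "chr1", start = 9e7, end = 9.1e7,
                       gene = "DEL1")
  calls2 <- call_gene_cnv(seg_wgd, g2)
  expect_equal(calls2$predominant_cn, 4L)
  expect_equal(calls2$call, "deletion")
})

test_that("BED gene intervals convert to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tEGFR", path)
  bed <- read_gene_bed(path)
  expect_equal(bed$start, 100)
  expect_equal(bed$end, 200)
  expect_equal(bed$gene, "EGFR")
})
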