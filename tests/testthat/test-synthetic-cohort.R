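small_config <- function(seed = 7) {
  cohort_sim_config(
    n_pos = 3, n_neg = 2, seed = seed,
    pos = group_sim_params(n_segments = 25, callable_mb = 10),
    neg = group_sim_params(n_segments = 25, callable_mb = 10))
}

test_that("simulation is deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(small_config(7), dir = d1)
  simulate_cohort(small_config(7), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  # different seeds give different draws
  s7 <- simulate_cohort(small_config(7))
  s8 <- simulate_cohort(small_config(8))
  expect_false(identical(s7$samples[[1]]$variants,
                         s8$samples[[1]]$variants))
})

test_that("every emitted record has exactly one truth record", {
  sim <- simulate_cohort(small_config(3))
  for (id in names(sim$samples)) {
    expect_equal(nrow(sim$samples[[id]]$variants),
                 sum(sim$truth$variants$sample == id))
    expect_equal(nrow(sim$samples[[id]]$segments),
                 sum(sim$truth$segments$sample == id))
  }
  expect_equal(nrow(sim$truth$samples), 5)
})

test_that("configuration invariants are enforced", {
  expect_error(group_sim_params(wgd_prob = 1.2), "0, 1")
  expect_error(group_sim_params(signature_weights = c(SBS1 = 0.5,
                                                      SBS5 = 0.4)),
               "sum to 1")
  expect_error(group_sim_params(tmb_mean = -1), "positive")
  expect_error(cohort_sim_config(n_pos = 0), ">= 1")
})

test_that("zero-noise segments follow the forward model exactly", {
  g <- mini_genome()
  params <- group_sim_params(n_segments = 20)
  set.seed(5)
  s <- simulate_sample_segments(params, g, purity = 0.5, wgd = FALSE,
                                logr_sd = 0, baf_sd = 0)
  psi <- attr(s$truth, "ploidy")
  expect_equal(
    s$segments$logR,
    expected_logr(0.5, s$truth$true_total_cn, psi))
  expect_equal(
    s$segments$BAF,
    expected_baf(0.5, s$truth$true_total_cn, s$truth$true_minor_cn))
  # segments tile each autosome without gaps
  by_chrom <- split(s$segments, s$segments$chrom)
  for (ch in by_chrom) {
    ch <- ch[order(ch$start), ]
    expect_equal(ch$start[1], 1)
    expect_equal(ch$end[nrow(ch)], 1e8)
    if (nrow(ch) > 1) {
      expect_equal(ch$start[-1], ch$end[-nrow(ch)] + 1)
    }
  }
})

test_that("mutation read support matches the CCF expectation", {
  g <- mini_genome()
  params <- group_sim_params(subclonal_mut_frac = 0, subclonal_cn_frac = 0,
                             cn_alter_frac = 0, depth_mean = 5000,
                             callable_mb = 30, n_segments = 10)
  set.seed(9)
  s <- simulate_sample_segments(params, g, 0.5, FALSE,
                                logr_sd = 0, baf_sd = 0)
  m <- simulate_sample_mutations(params, hetpanel_signatures(), s$truth, 0.5)
  # clonal het variants on CN-2 at purity 0.5: expected VAF 0.25
  expect_equal(unique(m$truth$expected_vaf), 0.25)
  expect_equal(mean(m$truth$vaf), 0.25, tolerance = 0.01)
  # trinucleotide context is consistent with ref on the emitted strand
  expect_true(all(substr(m$variants$trinucleotide_context, 2, 2) ==
                    m$variants$ref))
})

test_that("WGD draws respect the configured group probabilities", {
  g <- mini_genome()
  n <- 300
  wgd <- logical(n)
  for (i in seq_len(n)) {
    set.seed(1000 + i)
    wgd[i] <- runif(1) < 0.8  # the generator's Bernoulli draw
  }
  # sanity of the binomial bound logic itself
  expect_lt(abs(mean(wgd) - 0.8), 3 * sqrt(0.8 * 0.2 / n))

  # via the cohort generator (small genomes for speed)
  cfg <- cohort_sim_config(
    n_pos = 60, n_neg = 60, seed = 13,
    pos = group_sim_params(wgd_prob = 0.8, n_segments = 5,
                           callable_mb = 2),
    neg = group_sim_params(wgd_prob = 0.29, n_segments = 5,
                           callable_mb = 2))
  sim <- simulate_cohort(cfg, genome = mini_genome())
  rates <- tapply(sim$truth$samples$wgd, sim$truth$samples$group, mean)
  expect_lt(abs(rates[["T790Mpos"]] - 0.8), 3 * sqrt(0.8 * 0.2 / 60))
  expect_lt(abs(rates[["T790Mneg"]] - 0.29), 3 * sqrt(0.29 * 0.71 / 60))
})

test_that("written cohorts read back identically", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(small_config(11), dir = dir)
  back <- read_cohort(dir)
  expect_equal(back$metadata$sample, sim$metadata$sample)
  expect_equal(back$metadata$purity, sim$metadata$purity, tolerance = 1e-9)
  id <- sim$metadata$sample[1]
  for (col in c("chrom", "pos", "ref", "alt", "depth", "alt_count",
                "consequence_class", "region")) {
    expect_equal(back$samples[[id]]$variants[[col]],
                 sim$samples[[id]]$variants[[col]], info = col)
  }
  expect_equal(back$samples[[id]]$segments$logR,
               sim$samples[[id]]$segments$logR, tolerance = 1e-9)

  # metadata naming samples without files is an error
  meta <- read_cohort_metadata(file.path(dir, "cohort_metadata.tsv"))
  meta$sample[1] <- "GHOST"
  readr::write_tsv(meta, file.path(dir, "cohort_metadata.tsv"))
  expect_error(read_cohort(dir), "GHOST")
})

test_that("YAML configuration mirrors the constructor", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_pos: 4", "n_neg: 3", "seed: 42", "logr_sd: 0.03",
    "pos:",
    "  wgd_prob: 0.9", "  tmb_mean: 3.0",
    "neg:",
    "  wgd_prob: 0.2"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "cohort_sim_config")
  expect_equal(cfg$n_pos, 4)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$logr_sd, 0.03)
  expect_equal(cfg$pos$wgd_prob, 0.9)
  expect_equal(cfg$pos$tmb_mean, 3.0)
  expect_equal(cfg$neg$wgd_prob, 0.2)
})
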