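test_that("group comparisons use Wilcoxon for continuous, Fisher for binary", {
  d <- tibble::tibble(
    group = rep(c("T790Mneg", "T790Mpos"), each = 6),
    same = rep(c(1, 2, 3, 4, 5, 6), 2),
    shifted = c(1:6, 11:16),
    flag = c(rep(0, 5), 1, rep(1, 5), 0))
  st <- compare_groups(d, markers = c("same", "shifted", "flag"),
                       binary = "flag")
  expect_equal(st$p[st$marker == "same"], 1)  # identical multisets
  expect_equal(st$test[st$marker == "shifted"], "wilcoxon")
  expect_equal(st$test[st$marker == "flag"], "fisher")
  expect_equal(st$median_pos[st$marker == "shifted"], 13.5)
  expect_lt(st$p[st$marker == "shifted"], 0.01)

  expect_error(compare_groups(dplyr::mutate(d, group = "one")), "two groups")
})

test_that("exact Wilcoxon equals full permutation enumeration", {
  set.seed(202)
  for (k in 1:15) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- round(runif(n1), 3)
    y <- round(runif(n2) + 0.2, 3)
    d <- tibble::tibble(group = rep(c("pos", "neg"), c(n1, n2)),
                        m = c(x, y))
    p_pkg <- compare_groups(d, markers = "m", positive = "pos")$p
    expect_equal(p_pkg, oracle_wilcoxon_perm(x, y), tolerance = 1e-9)
  }
})

test_that("Fisher table statistics match the cross-product odds ratio", {
  d <- tibble::tibble(
    group = rep(c("T790Mpos", "T790Mneg"), c(25, 14)),
    wgd = c(rep(1, 20), rep(0, 5), rep(1, 4), rep(0, 10)))
  st <- compare_groups(d, markers = "wgd", binary = "wgd")
  # sample odds ratio (20 * 10) / (5 * 4) = 10
  a <- 20; b <- 5; cc <- 4; dd <- 10
  expect_equal((a * dd) / (b * cc), 10)
  expect_equal(st$p, fisher.test(matrix(c(20, 5, 4, 10), 2))$p.value)
  expect_equal(st$median_pos, 0.8)
  expect_equal(st$median_neg, 4 / 14)
})

test_that("BH adjustment matches the hand-computed step-up", {
  out <- adjust_bh(c(0.005, 0.01, 0.03, 0.04))
  expect_equal(out$q, c(0.02, 0.02, 0.04, 0.04))
  expect_true(all(out$significant))

  expect_false(any(adjust_bh(c(0.9, 0.95))$significant))
  expect_equal(adjust_bh(0.05)$q, 0.05)
  expect_equal(nrow(adjust_bh(numeric(0))), 0)
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
})

test_that("BH equals the brute-force oracle on random vectors", {
  set.seed(303)
  for (k in 1:300) {
    p <- runif(sample(1:25, 1))
    expect_equal(adjust_bh(p)$q, oracle_bh(p), tolerance = 1e-12)
  }
  # q-values are monotone in sorted p order
  p <- runif(50)
  q <- adjust_bh(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("correlation pruning flags signed R above threshold", {
  set.seed(404)
  d <- tibble::tibble(a = rnorm(30))
  d$b <- d$a                       # duplicate: R = 1
  d$c <- -d$a                      # negation: R = -1, not flagged
  d$e <- rnorm(30)
  d$z <- rep(1, 30)                # zero variance
  pr <- pearson_prune(d, features = c("a", "b", "c", "e", "z"))
  flag_pairs <- paste(pr$flagged$feature_a, pr$flagged$feature_b)
  expect_true("a b" %in% flag_pairs)
  expect_false(any(grepl("c", flag_pairs)))
  expect_true(is.na(pr$r$r[pr$r$feature_a == "a" & pr$r$feature_b == "z"]))
  expect_equal(pr$r$r[pr$r$feature_a == "a" & pr$r$feature_b == "c"], -1)
})

test_that("AUC equals brute-force pair counting with half ties", {
  a <- roc_auc(c(2, 3, 4, 1, 2, 3), rep(c("pos", "neg"), each = 3),
               positive = "pos")
  expect_equal(a$auc, 7 / 9)

  perfect <- roc_auc(c(5, 6, 7, 1, 2, 3), rep(c("pos", "neg"), each = 3),
                     positive = "pos")
  expect_equal(perfect$auc, 1)

  ties <- roc_auc(rep(1, 8), rep(c("pos", "neg"), each = 4),
                  positive = "pos")
  expect_equal(ties$auc, 0.5)

  # anti-discriminative scores are not auto-flipped
  anti <- roc_auc(c(1, 2, 3, 5, 6, 7), rep(c("pos", "neg"), each = 3),
                  positive = "pos")
  expect_equal(anti$auc, 0)

  expect_error(roc_auc(1:3, rep("pos", 3)), "both classes")

  set.seed(505)
  for (k in 1:25) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    sc <- c(sample(1:6, n1, TRUE), sample(1:6, n2, TRUE))
    lab <- rep(c("pos", "neg"), c(n1, n2))
    expect_equal(roc_auc(sc, lab, positive = "pos")$auc,
                 oracle_auc(sc[seq_len(n1)], sc[n1 + seq_len(n2)]),
                 tolerance = 1e-12)
  }
})

test_that("DeLong intervals bracket the AUC", {
  set.seed(606)
  sc <- c(rnorm(20, 1), rnorm(20))
  lab <- rep(c("pos", "neg"), each = 20)
  a <- roc_auc(sc, lab, positive = "pos")
  expect_true(a$auc_lo <= a$auc && a$auc <= a$auc_hi)
  expect_true(a$auc_lo >= 0 && a$auc_hi <= 1)
})

test_that("the IRLS solver agrees with glm on well-conditioned data", {
  set.seed(707)
  X <- cbind(rnorm(200), rnorm(200))
  y <- rbinom(200, 1, plogis(0.5 + X %*% c(1, -0.5)))
  beta <- hetpanel:::irls_logistic(X, y, lambda = 1e-6)
  ref <- coef(glm(y ~ X, family = binomial()))
  expect_equal(unname(beta), unname(ref), tolerance = 1e-4)
})

test_that("LOOCV logistic model validates inputs and scores held-out samples", {
  set.seed(808)
  n <- 40
  d <- tibble::tibble(
    sample = sprintf("S%02d", 1:n),
    group = rep(c("T790Mpos", "T790Mneg"), each = n / 2),
    f1 = c(rnorm(n / 2, 3), rnorm(n / 2, 0)),  # 3 SD separation
    f2 = rnorm(n))
  fit <- loocv_logistic(d, features = c("f1", "f2"), positive = "T790Mpos")
  expect_equal(nrow(fit$predictions), n)
  expect_gte(fit$auc$auc, 0.9)

  # invariant to feature scaling (fold-wise standardization)
  d2 <- dplyr::mutate(d, f1 = f1 * 1000, f2 = f2 / 77)
  fit2 <- loocv_logistic(d2, features = c("f1", "f2"),
                         positive = "T790Mpos")
  expect_equal(fit2$predictions$looc_probability,
               fit$predictions$looc_probability, tolerance = 1e-6)

  # invariant to sample order
  perm <- sample(n)
  fit3 <- loocv_logistic(d[perm, ], features = c("f1", "f2"),
                         positive = "T790Mpos")
  m <- match(fit$predictions$sample, fit3$predictions$sample)
  expect_equal(fit3$predictions$looc_probability[m],
               fit$predictions$looc_probability, tolerance = 1e-9)

  expect_error(loocv_logistic(d[1:4, ], features = "f1"), "at least 6")

  # correlated feature pairs are rejected
  d$f3 <- d$f1 + rnorm(n, sd = 0.01)
  expect_error(loocv_logistic(d, features = c("f1", "f3"),
                              positive = "T790Mpos"), "correlation")

  # missing values drop samples with a message
  d$f2[3] <- NA
  expect_message(fit4 <- loocv_logistic(d, features = c("f1", "f2"),
                                        positive = "T790Mpos"), "dropped")
  expect_equal(nrow(fit4$predictions), n - 1)
})
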