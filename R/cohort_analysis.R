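#' Two-group marker comparison
#'
#' Continuous markers are compared with the two-sided Wilcoxon rank-sum
#' test (exact when `n1 + n2 <= 20` and untied, otherwise the
#' tie-corrected normal approximation); binary markers with the
#' two-sided Fisher exact test on the 2x2 table. Marker typing is
#' declared through `binary`, never inferred. Constant markers give
#' p = 1.
#'
#' @param data Tibble with one row per sample.
#' @param label Name of the group label column.
#' @param markers Marker columns to test (default: all numeric/logical
#'   columns except the label).
#' @param binary Character vector naming the markers to treat as binary.
#' @param positive Label value of the positive group (default: the last
#'   of the sorted unique labels, e.g. `"T790Mpos"` over `"T790Mneg"`).
#' @return Tibble `marker`, `type`, `median_pos`, `median_neg`, `test`,
#'   `p`. For binary markers the "medians" are the positive-class
#'   proportions in each group.
#' @export
compare_groups <- function(data, label = "group", markers = NULL,
                           binary = character(), positive = NULL) {
  labs <- data[[label]]
  lv <- sort(unique(labs))
  if (length(lv) != 2) abort("exactly two groups are required")
  positive <- positive %||% lv[length(lv)]
  if (!positive %in% lv) abort("positive label not present in data")
  negative <- setdiff(lv, positive)
  if (sum(labs == positive) == 0 || sum(labs == negative) == 0) {
    abort("both groups must be non-empty")
  }
  if (is.null(markers)) {
    is_num <- vapply(data, function(x) is.numeric(x) || is.logical(x),
                     logical(1))
    markers <- setdiff(names(data)[is_num], label)
  }
  purrr::map_dfr(markers, function(mk) {
    x <- data[[mk]]
    keep <- !is.na(x)
    xp <- x[keep & labs == positive]
    xn <- x[keep & labs == negative]
    if (mk %in% binary) {
      tab <- matrix(c(sum(xp == 1 | xp == TRUE), sum(!(xp == 1 | xp == TRUE)),
                      sum(xn == 1 | xn == TRUE), sum(!(xn == 1 | xn == TRUE))),
                    nrow = 2)
      p <- if (length(unique(x[keep])) < 2) 1 else fisher.test(tab)$p.value
      tibble::tibble(marker = mk, type = "binary",
                     median_pos = mean(xp == 1 | xp == TRUE),
                     median_neg = mean(xn == 1 | xn == TRUE),
                     test = "fisher", p = p)
    } else {
      p <- if (length(unique(x[keep])) < 2) {
        1
      } else {
        exact <- (length(xp) + length(xn) <= 20) &&
          !anyDuplicated(c(xp, xn))
        suppressWarnings(
          wilcox.test(xp, xn, exact = exact, correct = FALSE)$p.value)
      }
      tibble::tibble(marker = mk, type = "continuous",
                     median_pos = median(xp), median_neg = median(xn),
                     test = "wilcoxon", p = p)
    }
  })
}

#' Benjamini-Hochberg adjustment with FDR flags
#'
#' Step-up BH q-values (monotone by construction) and significance flags
#' at the given false discovery rate.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param fdr False discovery rate (default 0.10).
#' @return Tibble `p`, `q`, `significant`.
#' @export
adjust_bh <- function(p, fdr = 0.10) {
  if (length(p) == 0) {
    return(tibble::tibble(p = double(), q = double(),
                          significant = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = !is.na(q) & q <= fdr)
}

#' Pairwise Pearson correlation pruning
#'
#' Computes the pairwise Pearson correlation matrix over complete cases
#' per pair and flags pairs with `R > threshold` (signed, as printed in
#' correlation tables; strong negative correlations are not flagged).
#' Zero-variance features give `NA` correlations and are never flagged.
#'
#' @param data Tibble with one row per sample.
#' @param features Feature columns (default: all numeric columns).
#' @param threshold Flagging threshold on R (default 0.5).
#' @param min_complete Minimum complete pairs per correlation (default 3).
#' @return List `r` (correlation tibble in long form: `feature_a`,
#'   `feature_b`, `r`) and `flagged` (subset with `r > threshold`).
#' @export
pearson_prune <- function(data, features = NULL, threshold = 0.5,
                          min_complete = 3) {
  if (is.null(features)) {
    features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  pairs <- utils::combn(features, 2)
  r_long <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- data[[pairs[1, k]]]
    b <- data[[pairs[2, k]]]
    cc <- complete.cases(a, b)
    r <- if (sum(cc) < min_complete || sd(a[cc]) == 0 || sd(b[cc]) == 0) {
      NA_real_
    } else {
      cor(a[cc], b[cc], method = "pearson")
    }
    tibble::tibble(feature_a = pairs[1, k], feature_b = pairs[2, k], r = r)
  })
  list(r = r_long,
       flagged = dplyr::filter(r_long, !is.na(.data$r),
                               .data$r > threshold))
}

#' ROC AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney statistic scaled by `n1 * n2` with ties
#' counted one-half, oriented so that higher scores indicate the
#' positive class (never auto-flipped below 0.5). The confidence
#' interval uses the DeLong variance estimate (via pROC). Degenerate
#' all-tied scores give AUC 0.5.
#'
#' @param scores Numeric predictor.
#' @param labels Group labels (two classes).
#' @param positive Positive class (default: last of sorted unique
#'   labels).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `auc`, `auc_lo`, `auc_hi`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL, conf_level = 0.95) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  lv <- sort(unique(labels))
  if (length(lv) != 2) abort("both classes must be present")
  positive <- positive %||% lv[length(lv)]
  negative <- setdiff(lv, positive)
  n_pos <- sum(labels == positive)
  n_neg <- sum(labels == negative)
  if (sd(scores) == 0) {
    return(tibble::tibble(auc = 0.5, auc_lo = 0.5, auc_hi = 0.5,
                          n_pos = n_pos, n_neg = n_neg))
  }
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong", conf.level = conf_level)))
  tibble::tibble(auc = as.numeric(pROC::auc(r)),
                 auc_lo = max(ci[1], 0), auc_hi = min(ci[3], 1),
                 n_pos = n_pos, n_neg = n_neg)
}

# Maximum-likelihood logistic regression by IRLS with a small ridge term
# for separable folds; deterministic. X includes no intercept column --
# it is added here.
irls_logistic <- function(X, y, lambda = 1e-6, max_iter = 100,
                          tol = 1e-10) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  pen <- diag(lambda, ncol(X1))
  pen[1, 1] <- 0  # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new_beta <- tryCatch(
      solve(crossprod(X1, X1 * w) + pen, crossprod(X1, w * z)),
      error = function(e) NULL)
    if (is.null(new_beta)) abort("IRLS normal equations singular")
    new_beta <- drop(new_beta)
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) return(beta)
    # separable data drifts to infinity; the ridge keeps it finite but
    # convergence by delta may be slow -- cap on likelihood plateau
    if (it == max_iter) break
  }
  beta
}

#' Leave-one-out cross-validated logistic biomarker model
#'
#' For each held-out sample, features are z-standardized on the training
#' fold only, a maximum-likelihood logistic regression is fitted by
#' iteratively reweighted least squares with a ridge jitter
#' (`lambda = 1e-6`) guarding against separability, and the held-out
#' probability of the positive class is predicted. Pooled probabilities
#' are scored by [roc_auc()] with a DeLong interval. Fully deterministic.
#'
#' @param data Tibble with one row per sample.
#' @param features Feature column names.
#' @param label Group label column (default `"group"`).
#' @param positive Positive class (default: last of sorted unique
#'   labels).
#' @param max_r Feature pairs correlating above this (signed Pearson R,
#'   see [pearson_prune()]) make the feature set invalid (default 0.5;
#'   `Inf` disables the check).
#' @param lambda Ridge jitter (default 1e-6).
#' @return List `predictions` (tibble `sample`, `label`, `looc_probability`),
#'   `auc` (tibble from [roc_auc()]), `features`, `n_dropped` (samples
#'   dropped for missing feature values).
#' @export
loocv_logistic <- function(data, features, label = "group",
                           positive = NULL, max_r = 0.5, lambda = 1e-6) {
  missing_cols <- setdiff(c(features, label), names(data))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  cc <- complete.cases(data[, c(features, label)])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("%d sample(s) dropped for missing marker values",
                   n_dropped))
  }
  d <- data[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < 6) abort(sprintf("LOOCV needs at least 6 complete samples, have %d", n))
  labs <- d[[label]]
  lv <- sort(unique(labs))
  if (length(lv) != 2) abort("exactly two classes are required")
  positive <- positive %||% lv[length(lv)]
  y <- as.numeric(labs == positive)
  if (is.finite(max_r)) {
    flagged <- pearson_prune(d, features, threshold = max_r)$flagged
    if (nrow(flagged) > 0) {
      abort(paste0("feature pairs exceed the correlation threshold: ",
                   paste(paste(flagged$feature_a, flagged$feature_b,
                               sep = "~"), collapse = ", ")))
    }
  }
  X <- as.matrix(d[, features, drop = FALSE])
  prob <- vapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    zte <- (X[i, ] - mu) / sdv
    beta <- irls_logistic(Ztr, y[-i], lambda = lambda)
    plogis(drop(c(1, zte) %*% beta))
  }, numeric(1))
  sample_ids <- if ("sample" %in% names(d)) d$sample else as.character(seq_len(n))
  list(predictions = tibble::tibble(sample = sample_ids, label = labs,
                                    looc_probability = prob),
       auc = roc_auc(prob, labs, positive = positive),
       features = features, n_dropped = n_dropped)
}
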