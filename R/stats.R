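## Cohort-comparison statistics: exact 2x2 tests in log space, Welch t from
## summaries, confounder-adjusted prevalence comparison, bootstrap elastic-net
## variable usage, and the feature-by-covariate association matrix.

#' Fisher's exact test on a 2x2 table (two-sided, log-space)
#'
#' Two-sided p by the minimum-likelihood convention: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one, accumulated in log space so that extreme tables
#' (p ~ 1e-80 and far beyond) do not underflow. A zero margin returns p = 1
#' with a degenerate flag.
#'
#' @param table 2x2 integer matrix, or four counts `a, b, c, d` (row-wise).
#' @return List: `p`, `log10_p`, `odds_ratio` (sample cross-product ratio),
#'   `degenerate`.
#' @export
fisher_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != round(table)))
    format_error("fisher_2x2: counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b            # row 1 total
  n <- c + d            # row 2 total
  k <- a + c            # column 1 total
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(list(p = 1, log10_p = 0, odds_ratio = NaN, degenerate = TRUE))
  }
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  log_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  ## relative tolerance as in the classical implementation of the test
  keep <- logp <= log_obs + log(1 + 1e-7)
  lp <- logsumexp(logp[keep])
  p <- min(exp(lp), 1)
  list(p = p, log10_p = lp / log(10), odds_ratio = (a * d) / (b * c),
       degenerate = FALSE)
}

#' Welch's t-test from summary statistics
#'
#' Welch statistic with Satterthwaite degrees of freedom from group means,
#' standard deviations and sizes; two-sided p from the t distribution. The
#' log10 p is also returned for comparisons far below double precision.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries; `sd > 0`, `n >= 2`.
#' @return List: `t`, `df`, `p`, `log10_p`.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) format_error("welch_from_summary: need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) format_error("welch_from_summary: need sd > 0")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  logp <- stats::pt(-abs(t), df, log.p = TRUE) + log(2)
  list(t = t, df = df, p = exp(logp), log10_p = logp / log(10))
}

#' Compare binary feature prevalence between cohorts
#'
#' For each binary feature, an unadjusted Fisher exact p on the 2x2 table and
#' an adjusted p from logistic regression with the cohort status as the
#' response, the feature as the main factor and the covariates as additional
#' terms; BH FDR across features for both p columns. Complete separation is
#' flagged (adjusted p undefined; the direction is still reported as the
#' continuity-corrected log-odds of the 2x2 table).
#'
#' @param features Samples x features 0/1 matrix (or a single vector).
#' @param cohort Two-level factor/character over samples.
#' @param covariates Optional data.frame of per-sample covariates.
#' @return Data frame: `item`, `k_1`, `n_1`, `k_2`, `n_2` (counts per cohort),
#'   `fisher_p`, `fisher_fdr`, `adjusted_p`, `adjusted_fdr`, `log_odds`,
#'   `separation`.
#' @export
prevalence_compare <- function(features, cohort, covariates = NULL) {
  if (is.vector(features)) features <- matrix(features, ncol = 1,
                                              dimnames = list(NULL, "feature"))
  cohort <- factor(cohort)
  if (nlevels(cohort) != 2L) format_error("prevalence_compare: need exactly 2 cohorts")
  y <- as.integer(cohort == levels(cohort)[2L])
  rows <- lapply(colnames(features), function(nm) {
    x <- features[, nm]
    k <- tapply(x, cohort, sum); n <- tapply(x, cohort, length)
    fp <- fisher_2x2(matrix(c(k[1], n[1] - k[1], k[2], n[2] - k[2]), 2, 2, byrow = TRUE))
    dat <- data.frame(y = y, x = x)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    sep <- FALSE; ap <- NA_real_; lo <- NA_real_
    if (stats::sd(x) == 0) {
      warning(sprintf("feature %s is constant; adjusted test skipped", nm), call. = FALSE)
    } else {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
      co <- summary(fit)$coefficients
      if ("x" %in% rownames(co)) {
        lo <- co["x", "Estimate"]
        ap <- co["x", "Pr(>|z|)"]
        if (abs(lo) > 10 || co["x", "Std. Error"] > 100) {
          sep <- TRUE
          ap <- NA_real_
          ## continuity-corrected log-odds for a finite direction estimate
          lo <- log(((k[2] + 0.5) / (n[2] - k[2] + 0.5)) /
                    ((k[1] + 0.5) / (n[1] - k[1] + 0.5)))
        }
      }
    }
    data.frame(item = nm, k_1 = k[1], n_1 = n[1], k_2 = k[2], n_2 = n[2],
               fisher_p = fp$p, adjusted_p = ap, log_odds = lo,
               separation = sep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fisher_fdr <- stats::p.adjust(out$fisher_p, "BH")
  out$adjusted_fdr <- NA_real_
  ok <- !is.na(out$adjusted_p)
  out$adjusted_fdr[ok] <- stats::p.adjust(out$adjusted_p[ok], "BH")
  out
}

#' Bootstrap elastic-net variable usage
#'
#' For each of `n_boot` bootstrap resamples, fits an elastic-net-penalised
#' logistic regression of the cohort label on the (internally standardised)
#' feature matrix, with the penalty chosen by internal cross-validation, and
#' records which features have nonzero coefficients. The usage of a feature is
#' the percentage of bootstraps in which it was selected.
#'
#' @param X Samples x features numeric matrix (>= 2 features). Constant
#'   features get usage 0 with a warning.
#' @param y Two-level response (cohort label).
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param nfolds Cross-validation folds for the penalty (default 5).
#' @param lambda_choice `"lambda.1se"` (default; the parsimonious CV choice,
#'   which keeps selection stable when a strong predictor makes the data
#'   separable) or `"lambda.min"`.
#' @param type_measure Cross-validation loss: `"class"` (misclassification
#'   error, the default — its flatter CV curve yields sparser, more stable
#'   selection) or `"deviance"`.
#' @param seed Integer seed.
#' @return Named numeric vector of usage percentages in `[0, 100]`. Highly
#'   collinear feature pairs (|r| > 0.99) trigger a collinearity note.
#' @export
variable_usage <- function(X, y, n_boot = 500L, alpha = 0.5, nfolds = 5L,
                           lambda_choice = c("lambda.1se", "lambda.min"),
                           type_measure = c("class", "deviance"),
                           seed = 1L) {
  lambda_choice <- match.arg(lambda_choice)
  type_measure <- match.arg(type_measure)
  X <- as.matrix(X)
  if (ncol(X) < 2L) format_error("variable_usage: need >= 2 features")
  y <- factor(y)
  if (nlevels(y) != 2L) format_error("variable_usage: response must have 2 levels")
  const <- apply(X, 2, stats::sd) == 0
  if (any(const))
    warning(sprintf("constant feature(s) get usage 0: %s",
                    paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
  Xa <- X[, !const, drop = FALSE]
  cm <- stats::cor(Xa)
  high <- which(abs(cm) > 0.99 & upper.tri(cm), arr.ind = TRUE)
  if (nrow(high) > 0)
    message(sprintf("collinearity note: %d feature pair(s) with |r| > 0.99 (e.g. %s ~ %s); usage may split between them",
                    nrow(high), colnames(Xa)[high[1, 1]], colnames(Xa)[high[1, 2]]))
  counts <- numeric(ncol(Xa))
  with_seed(derive_seed(seed, 31L), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(nrow(Xa), replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
      }
      cv <- glmnet::cv.glmnet(Xa[idx, , drop = FALSE], y[idx], family = "binomial",
                              alpha = alpha, nfolds = nfolds, standardize = TRUE,
                              type.measure = type_measure)
      beta <- stats::coef(cv, s = lambda_choice)[-1L, 1L]
      counts <- counts + (beta != 0)
    }
  })
  usage <- stats::setNames(numeric(ncol(X)), colnames(X))
  usage[!const] <- 100 * counts / n_boot
  usage
}

#' Feature-by-covariate association matrix
#'
#' Regresses each molecular feature on all clinical covariates jointly —
#' logistic regression when the feature is binary (exactly two distinct
#' values), ordinary linear regression otherwise — and tabulates the per-term
#' p-values, coefficients and `-log10(p)`, mirroring a multivariate feature
#' heatmap. Rank-deficient designs have the aliased terms dropped and logged.
#'
#' @param features Samples x features matrix or data.frame.
#' @param covariates Samples x covariates data.frame.
#' @return List of class `multivariate_report`: matrices `p`, `coef`,
#'   `neglog10_p` (features x covariate terms) and `skipped` (constant
#'   features).
#' @export
feature_covariate_matrix <- function(features, covariates) {
  features <- as.data.frame(features)
  covariates <- as.data.frame(covariates)
  if (nrow(features) != nrow(covariates))
    format_error("feature_covariate_matrix: sample mismatch")
  terms_ref <- colnames(stats::model.matrix(~., data = covariates))[-1L]
  p_mat <- coef_mat <- matrix(NA_real_, ncol(features), length(terms_ref),
                              dimnames = list(colnames(features), terms_ref))
  skipped <- character(0)
  for (nm in colnames(features)) {
    f <- features[[nm]]
    if (length(unique(f)) < 2L) {
      warning(sprintf("feature %s is constant; skipped", nm), call. = FALSE)
      skipped <- c(skipped, nm)
      next
    }
    dat <- cbind(data.frame(.y = f), covariates)
    binary <- length(unique(f)) == 2L
    fit <- if (binary) {
      suppressWarnings(stats::glm(factor(.y) ~ ., data = dat, family = stats::binomial()))
    } else {
      stats::lm(.y ~ ., data = dat)
    }
    co <- summary(fit)$coefficients
    aliased <- setdiff(terms_ref, rownames(co))
    if (length(aliased))
      message(sprintf("feature %s: dropped rank-deficient term(s) %s",
                      nm, paste(aliased, collapse = ", ")))
    common <- intersect(terms_ref, rownames(co))
    p_mat[nm, common] <- co[common, 4L]
    coef_mat[nm, common] <- co[common, 1L]
  }
  structure(list(p = p_mat, coef = coef_mat,
                 neglog10_p = -log10(p_mat), skipped = skipped),
            class = "multivariate_report")
}

#' @export
print.multivariate_report <- function(x, ...) {
  cat("Feature-by-covariate association (-log10 p):\n")
  print(round(x$neglog10_p, 2))
  invisible(x)
}
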