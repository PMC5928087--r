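## Covariate-adjusted differential expression, rank-based pathway scores, and
## attribution of DE features to NMF factors by the max-correlation
## permutation test.

#' Two-stage low-expression / low-variance gene filter
#'
#' Removes the `floor(0.25 * G)` genes with the lowest mean, then the
#' `floor(0.25 * G')` genes with the lowest standard deviation among the
#' remainder. Ties are broken by lexicographic gene-id order, so the filter is
#' deterministic.
#'
#' @param expr Numeric matrix, genes x samples (>= 8 genes).
#' @param mean_frac,sd_frac Fractions removed at each stage (defaults 0.25).
#' @return The reduced matrix.
#' @export
filter_genes <- function(expr, mean_frac = 0.25, sd_frac = 0.25) {
  if (nrow(expr) < 8L) format_error("filter_genes: need >= 8 genes")
  mu <- rowMeans(expr)
  ord <- order(mu, rownames(expr))
  drop1 <- ord[seq_len(floor(mean_frac * nrow(expr)))]
  expr <- expr[-drop1, , drop = FALSE]
  sdv <- apply(expr, 1, stats::sd)
  ord2 <- order(sdv, rownames(expr))
  drop2 <- ord2[seq_len(floor(sd_frac * nrow(expr)))]
  expr[-drop2, , drop = FALSE]
}

#' Covariate-adjusted differential expression test
#'
#' Per feature, ordinary least squares of `feature ~ group + covariates`
#' (molecular subtype and tumor purity in the standard pipeline), a t-test on
#' the group coefficient, and Benjamini-Hochberg FDR across features. For
#' genes (log2-scale values) the effect is the log2 fold-change of the group
#' coefficient and a feature passes at `FDR < fdr` and fold-change > `fc` or
#' < `1/fc`; for pathway scores the effect is the score difference and the
#' pass rule is `FDR < fdr` and `|effect| > effect_min`.
#'
#' @param mat Features x samples matrix (genes on a log2 scale, or pathway
#'   scores).
#' @param group Two-level factor (or coercible) over samples; the effect is
#'   level 2 minus level 1.
#' @param covariates Optional data.frame of per-sample covariates; collinear
#'   columns are dropped deterministically (left to right) with a warning.
#' @param feature_type `"gene"` or `"pathway"`.
#' @param fdr FDR threshold (default 0.01).
#' @param fc Gene fold-change threshold (default 2).
#' @param effect_min Pathway score-difference threshold (default 0.2).
#' @return Data frame of class `de_result`: `feature`, `effect`, `t`, `p`,
#'   `fdr`, `pass`.
#' @export
de_test <- function(mat, group, covariates = NULL,
                    feature_type = c("gene", "pathway"),
                    fdr = 0.01, fc = 2, effect_min = 0.2) {
  feature_type <- match.arg(feature_type)
  group <- factor(group)
  if (nlevels(group) != 2L) format_error("de_test: group must have exactly 2 levels")
  if (min(table(group)) < 3L) format_error("de_test: need >= 3 samples per group")
  X <- stats::model.matrix(~group)
  if (!is.null(covariates)) {
    Xc <- stats::model.matrix(~., data = as.data.frame(covariates))[, -1L, drop = FALSE]
    X <- cbind(X, Xc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning(sprintf("de_test: dropping collinear covariate column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  Y <- t(mat)
  fit <- stats::lm.fit(X, Y)
  df_res <- nrow(X) - ncol(X)
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df_res
  XtXi <- chol2inv(chol(crossprod(X)))
  j <- which(colnames(X) == paste0("group", levels(group)[2L]))
  se <- sqrt(XtXi[j, j] * sigma2)
  beta <- as.matrix(fit$coefficients)[j, ]
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df_res)
  q <- stats::p.adjust(p, "BH")
  pass <- if (feature_type == "gene") {
    q < fdr & (2^beta > fc | 2^beta < 1 / fc)
  } else {
    q < fdr & abs(beta) > effect_min
  }
  structure(data.frame(feature = rownames(mat), effect = unname(beta),
                       t = unname(tstat), p = unname(p), fdr = unname(q),
                       pass = unname(pass), stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"), feature_type = feature_type)
}

#' Rank-based per-sample pathway scores
#'
#' A documented stand-in for single-sample gene-set scoring: within each
#' sample, genes are ranked, ranks are z-scored across genes, and a pathway's
#' score is the mean z of its member genes. The score of the all-genes set is
#' exactly 0 in every sample; gene sets with no expressed member are dropped
#' with a warning. Externally computed score matrices (e.g. exact GSVA) can be
#' supplied to downstream steps instead.
#'
#' @param expr Genes x samples expression matrix (any monotone scale).
#' @param genesets Named list of character vectors (see [read_gmt()]).
#' @return Pathways x samples score matrix.
#' @export
score_pathways <- function(expr, genesets) {
  rk <- apply(expr, 2, rank, ties.method = "average")
  z <- scale(rk)                          # per-sample (column) z-scoring
  keep <- vapply(genesets, function(g) length(intersect(g, rownames(expr))) > 0, TRUE)
  if (any(!keep))
    warning(sprintf("dropping %d pathway(s) with no expressed member gene", sum(!keep)),
            call. = FALSE)
  genesets <- genesets[keep]
  out <- t(vapply(genesets, function(g) {
    colMeans(z[rownames(expr) %in% g, , drop = FALSE])
  }, numeric(ncol(expr))))
  dimnames(out) <- list(names(genesets), colnames(expr))
  out
}

#' Associate features with NMF factors by max correlation with permutation FDR
#'
#' Computes the Pearson correlation of every feature with every factor's
#' per-sample weights; the test statistic is the maximum over factors (signed
#' by default, absolute optionally). The null distribution pools the max(r)
#' of all features over `n_perm` sample-reshuffled copies of the feature
#' matrix; the empirical p is add-one smoothed
#' (`p = (1 + #null >= obs) / (1 + N_null)`), followed by Benjamini-Hochberg
#' FDR. A gene is associated with its argmax factor iff `FDR <= fdr_max`; a
#' pathway iff `max r >= r_min`.
#'
#' @param mat Features x samples matrix.
#' @param H Factors x samples weight (fraction) matrix over the same samples.
#' @param n_perm Number of permutations (default 10).
#' @param seed Integer seed for the permutations.
#' @param mode `"signed"` (largest r, the default) or `"absolute"`.
#' @param feature_type `"gene"` (FDR rule) or `"pathway"` (r >= `r_min` rule).
#' @param fdr_max Gene association FDR cutoff (default 0.05).
#' @param r_min Pathway association correlation cutoff (default 0.6).
#' @return Data frame of class `association_result`: `feature`, `max_r`,
#'   `argmax_factor`, `p`, `fdr`, `associated`; the full feature x factor
#'   correlation matrix is in `attr(, "r_matrix")`.
#' @export
associate_features <- function(mat, H, n_perm = 10L, seed = 1L,
                               mode = c("signed", "absolute"),
                               feature_type = c("gene", "pathway"),
                               fdr_max = 0.05, r_min = 0.6) {
  mode <- match.arg(mode)
  feature_type <- match.arg(feature_type)
  if (ncol(mat) != ncol(H)) format_error("associate_features: sample mismatch")
  stat_of <- function(r) if (mode == "signed") apply(r, 1, max) else apply(abs(r), 1, max)
  sdv <- apply(mat, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat))
    warning(sprintf("%d zero-variance feature(s): correlation undefined, flagged",
                    sum(flat)), call. = FALSE)
  r <- matrix(NA_real_, nrow(mat), nrow(H), dimnames = list(rownames(mat), rownames(H)))
  r[!flat, ] <- stats::cor(t(mat[!flat, , drop = FALSE]), t(H))
  obs <- rep(NA_real_, nrow(mat))
  obs[!flat] <- stat_of(r[!flat, , drop = FALSE])
  null <- with_seed(derive_seed(seed, 17L), {
    unlist(lapply(seq_len(n_perm), function(b) {
      perm <- sample.int(ncol(mat))
      rp <- stats::cor(t(mat[!flat, perm, drop = FALSE]), t(H))
      stat_of(rp)
    }))
  })
  null_sorted <- sort(null)
  n_ge <- length(null) - findInterval(obs, null_sorted, left.open = TRUE)
  p <- (1 + n_ge) / (1 + length(null))
  p[flat] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!flat] <- stats::p.adjust(p[!flat], "BH")
  argmax <- rep(NA_character_, nrow(mat))
  pick <- if (mode == "signed") function(v) which.max(v) else function(v) which.max(abs(v))
  argmax[!flat] <- rownames(H)[apply(r[!flat, , drop = FALSE], 1, pick)]
  associated <- if (feature_type == "gene") !flat & q <= fdr_max
                else !flat & obs >= r_min
  structure(data.frame(feature = rownames(mat), max_r = obs,
                       argmax_factor = argmax, p = p, fdr = q,
                       associated = associated, stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"),
            r_matrix = r, mode = mode, feature_type = feature_type)
}

#' Categorise associated features by compartment class
#'
#' From the per-factor correlations and the factor compartment labels, the
#' per-class maxima `max_r_tumor` (tumor-intrinsic factors), `max_r_TME`
#' (TIL, stroma and normal-tissue factors) and `max_r_cohort` (cohort-specific
#' factors) are computed, and each feature is assigned exactly one category:
#' tumor-intrinsic if `max_r_tumor - max_r_TME > margin` and
#' `max_r_tumor > margin`; TME if the symmetric rule holds; cohort-specific if
#' `max_r_cohort` exceeds both others by more than `margin` and is itself
#' above `margin`; otherwise ambiguous. Default margin 0.2.
#'
#' @param assoc An `association_result` (carries the correlation matrix).
#' @param factor_labels Named character vector mapping factor name to
#'   compartment label, as produced by [attribute_compartments()]; every
#'   factor must be labelled (`unassigned` factors are excluded from all
#'   classes).
#' @param margin Decision margin (default 0.2).
#' @return The input data frame with columns `max_r_tumor`, `max_r_TME`,
#'   `max_r_cohort` and `category` added.
#' @export
categorize <- function(assoc, factor_labels, margin = 0.2) {
  r <- attr(assoc, "r_matrix")
  mode <- attr(assoc, "mode")
  if (is.null(r)) format_error("categorize: association result lacks its correlation matrix")
  if (anyNA(factor_labels[colnames(r)]))
    format_error("categorize: unlabeled factor '%s'",
                 colnames(r)[is.na(factor_labels[colnames(r)])][1])
  lab <- factor_labels[colnames(r)]
  classes <- list(
    tumor = startsWith(lab, "tumor_intrinsic"),
    TME = lab %in% c("TIL", "stroma", "healthy_normal", "adjacent_normal"),
    cohort = startsWith(lab, "cohort_specific"))
  class_max <- function(sel) {
    if (!any(sel)) return(rep(-Inf, nrow(r)))
    rr <- r[, sel, drop = FALSE]
    if (mode == "absolute") rr <- abs(rr)
    apply(rr, 1, max)
  }
  mt <- class_max(classes$tumor)
  mm <- class_max(classes$TME)
  mc <- class_max(classes$cohort)
  category <- ifelse(mt - mm > margin & mt > margin, "tumor_intrinsic",
              ifelse(mm - mt > margin & mm > margin, "TME",
              ifelse(mc - pmax(mt, mm) > margin & mc > margin, "cohort_specific",
                     "ambiguous")))
  assoc$max_r_tumor <- mt
  assoc$max_r_TME <- mm
  assoc$max_r_cohort <- mc
  assoc$category <- category
  assoc
}
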