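## Naive molecular classifier (NMC) and consensus subtype voting.

#' Fit a two-component Gaussian mixture to one marker gene
#'
#' EM for a two-component univariate Gaussian mixture over `log2(TPM+1)`
#' expression of a receptor marker (ESR1, PGR or ERBB2). The
#' immunohistochemistry-derived positive fraction is used as the prior: the
#' mixing weight is initialised at the prior and the component means at the
#' means of the values below/above the `1 - prior` quantile split. The
#' component with the larger mean is labelled positive; a sample is called
#' positive iff its posterior probability of the positive component exceeds
#' `0.5` (ties at exactly 0.5 are negative, for determinism).
#'
#' @param values Numeric vector of log2(TPM+1) expression, >= 10 finite values.
#' @param prior_pos_fraction Prior positive fraction in (0, 1).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000); non-convergence
#'   returns the last iterate with a warning.
#' @return Object of class `marker_mixture`: component means/SDs, mixing
#'   weight `pi_pos`, per-sample `posterior` of the positive component,
#'   `call` (logical), and the log-likelihood trace (non-decreasing).
#' @export
fit_marker_mixture <- function(values, prior_pos_fraction,
                               tol = 1e-6, max_iter = 1000L) {
  x <- values[is.finite(values)]
  if (length(x) < 10L) format_error("fit_marker_mixture: need >= 10 finite values")
  if (prior_pos_fraction <= 0 || prior_pos_fraction >= 1)
    format_error("fit_marker_mixture: prior must be in (0, 1)")
  if (stats::sd(x) == 0)
    format_error("fit_marker_mixture: degenerate input (zero variance)")

  split <- stats::quantile(x, 1 - prior_pos_fraction, names = FALSE)
  hi <- x > split
  if (!any(hi)) hi <- x >= max(x)           # all values equal to the split
  mu <- c(neg = mean(x[!hi]), pos = mean(x[hi]))
  sd_floor <- 1e-3
  sg <- c(neg = max(stats::sd(x[!hi]), sd_floor, na.rm = TRUE),
          pos = max(stats::sd(x[hi]), sd_floor, na.rm = TRUE))
  pi_pos <- prior_pos_fraction

  ll_trace <- numeric(0)
  post <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d_pos <- pi_pos * stats::dnorm(x, mu["pos"], sg["pos"])
    d_neg <- (1 - pi_pos) * stats::dnorm(x, mu["neg"], sg["neg"])
    tot <- d_pos + d_neg
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-8)
      format_error("EM log-likelihood decreased (%.6g -> %.6g)",
                   ll_trace[length(ll_trace)], ll)
    if (length(ll_trace) && abs(ll - ll_trace[length(ll_trace)]) < tol) {
      ll_trace <- c(ll_trace, ll)
      converged <- TRUE
      post <- d_pos / tot
      break
    }
    ll_trace <- c(ll_trace, ll)
    post <- d_pos / tot
    ## M step
    s1 <- sum(post)
    pi_pos <- min(max(s1 / length(x), 1e-6), 1 - 1e-6)
    mu["pos"] <- sum(post * x) / s1
    mu["neg"] <- sum((1 - post) * x) / (length(x) - s1)
    sg["pos"] <- max(sqrt(sum(post * (x - mu["pos"])^2) / s1), sd_floor)
    sg["neg"] <- max(sqrt(sum((1 - post) * (x - mu["neg"])^2) / (length(x) - s1)), sd_floor)
  }
  if (!converged) warning("EM did not converge; returning last iterate", call. = FALSE)

  ## positive = component with larger mean
  if (mu["pos"] < mu["neg"]) {
    mu <- rev(mu); sg <- rev(sg)
    names(mu) <- names(sg) <- c("neg", "pos")
    pi_pos <- 1 - pi_pos
    post <- 1 - post
  }
  ## posteriors for the full input vector (NA where value missing)
  full_post <- rep(NA_real_, length(values))
  full_post[is.finite(values)] <- post
  structure(list(mu_neg = unname(mu["neg"]), mu_pos = unname(mu["pos"]),
                 sigma_neg = unname(sg["neg"]), sigma_pos = unname(sg["pos"]),
                 pi_pos = pi_pos, posterior = full_post,
                 call = full_post > 0.5,
                 loglik = ll_trace, converged = converged),
            class = "marker_mixture")
}

#' @export
print.marker_mixture <- function(x, ...) {
  cat(sprintf("Two-component Gaussian mixture (EM, %d iterations%s)\n",
              length(x$loglik), if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  negative: N(%.3f, %.3f)  positive: N(%.3f, %.3f)  pi_pos = %.3f\n",
              x$mu_neg, x$sigma_neg, x$mu_pos, x$sigma_pos, x$pi_pos))
  cat(sprintf("  %d / %d samples called positive\n",
              sum(x$call, na.rm = TRUE), sum(!is.na(x$call))))
  invisible(x)
}

#' Naive molecular classifier (NMC)
#'
#' Calls a clinical subtype per sample from ESR1/PGR/ERBB2 expression mixture
#' fits plus ERBB2 copy number. Hormone-receptor positivity is ESR1-positive
#' OR PGR-positive; HER2 positivity is ERBB2-expression-positive OR ERBB2
#' copy number >= `cnv_amp_threshold`. Subtype: `ER+` (HR and not HER2),
#' `ER+/HER2+` (HR and HER2), `HER2+` (HER2 only), `TN` (neither).
#'
#' @param expr TPM expression matrix containing rows `ESR1`, `PGR`, `ERBB2`.
#' @param cnv Copy-number matrix with an `ERBB2` row (optional: `NULL` uses
#'   expression only).
#' @param ihc_fractions Named prior positive fractions, e.g.
#'   `c(ESR1 = .6, PGR = .5, ERBB2 = .2)`, typically the cohort IHC positive
#'   rates.
#' @param posterior_threshold Posterior call threshold (default 0.5).
#' @param cnv_amp_threshold Amplification threshold (default 6, `CN >= 6`).
#' @return List: `subtype` (named character), `fits` (per-marker
#'   `marker_mixture`), `positive` (sample x marker logical matrix).
#' @export
call_nmc <- function(expr, cnv = NULL, ihc_fractions,
                     posterior_threshold = 0.5, cnv_amp_threshold = 6) {
  markers <- c("ESR1", "PGR", "ERBB2")
  missing_m <- setdiff(markers, rownames(expr))
  if (length(missing_m))
    format_error("call_nmc: marker gene(s) %s absent from expression matrix",
                 paste(missing_m, collapse = ", "))
  if (!all(markers %in% names(ihc_fractions)))
    format_error("call_nmc: ihc_fractions must name %s", paste(markers, collapse = ", "))
  lv <- log_tpm(expr[markers, , drop = FALSE])
  fits <- lapply(markers, function(g) fit_marker_mixture(lv[g, ], ihc_fractions[[g]]))
  names(fits) <- markers
  pos <- vapply(fits, function(f) f$posterior > posterior_threshold,
                logical(ncol(expr)))
  rownames(pos) <- colnames(expr)
  her2_cn <- if (!is.null(cnv) && "ERBB2" %in% rownames(cnv)) {
    cnv["ERBB2", colnames(expr)] >= cnv_amp_threshold
  } else rep(FALSE, ncol(expr))
  hr <- pos[, "ESR1"] | pos[, "PGR"]
  her2 <- pos[, "ERBB2"] | her2_cn
  subtype <- ifelse(hr & !her2, "ER+",
             ifelse(hr & her2, "ER+/HER2+",
             ifelse(her2, "HER2+", "TN")))
  names(subtype) <- colnames(expr)
  list(subtype = subtype, fits = fits, positive = pos)
}

#' Map a PAM50 label to its compatible clinical subtypes
#'
#' LumA maps to ER+; LumB to ER+ and ER+/HER2+; Her2 to ER+/HER2+ and HER2+;
#' Basal to TN; Normal has no clinical image (empty set).
#'
#' @param label A PAM50 label (`LumA`, `LumB`, `Her2`, `Basal`, `Normal`).
#' @return Character vector of compatible clinical subtypes (possibly empty).
#' @export
map_pam50_to_clinical <- function(label) {
  map <- list(LumA = "ER+", LumB = c("ER+", "ER+/HER2+"),
              Her2 = c("ER+/HER2+", "HER2+"), Basal = "TN",
              Normal = character(0))
  if (length(label) != 1L || !label %in% names(map))
    format_error("map_pam50_to_clinical: unknown PAM50 label '%s'", paste(label, collapse = ","))
  map[[label]]
}

#' IHC clinical subtype from receptor calls
#' @param er,pr,her2 Character vectors in `{positive, negative, missing}`.
#' @return Character subtype, or `"missing"` where undetermined.
#' @export
ihc_subtype <- function(er, pr, her2) {
  hr <- ifelse(er == "positive" | pr == "positive", TRUE,
        ifelse(er == "negative" & pr == "negative", FALSE, NA))
  h2 <- ifelse(her2 == "positive", TRUE, ifelse(her2 == "negative", FALSE, NA))
  out <- ifelse(is.na(hr) | is.na(h2), "missing",
         ifelse(hr & !h2, "ER+", ifelse(hr & h2, "ER+/HER2+",
         ifelse(h2, "HER2+", "TN"))))
  out
}

#' Consensus subtype by majority vote of IHC, NMC and PAM50
#'
#' Votes are counted in clinical-subtype space: IHC and NMC each cast one vote
#' for their subtype; PAM50 casts a vote for every clinical subtype compatible
#' with its label (so LumB and Her2 vote for two subtypes but can never decide
#' alone). If IHC is available, the subtype reaching >= 2 votes wins (ties
#' that include the IHC subtype resolve to IHC); if no subtype reaches 2
#' votes — a three-way disagreement — the IHC result is used. If IHC is
#' missing, the NMC result is used.
#'
#' @param ihc,nmc Character vectors of clinical subtypes (`"missing"`/`NA`
#'   allowed for IHC; NMC must be defined).
#' @param pam50 Character vector of PAM50 labels (`"missing"`/`NA` allowed).
#' @return Data frame: `ihc`, `nmc`, `pam50`, `consensus`, `vote_trace`.
#' @export
consensus_subtype <- function(ihc, nmc, pam50) {
  n <- length(nmc)
  stopifnot(length(ihc) == n, length(pam50) == n)
  ihc[is.na(ihc)] <- "missing"; pam50[is.na(pam50)] <- "missing"
  if (any(is.na(nmc) | nmc == "missing"))
    format_error("consensus_subtype: NMC call must be defined for every sample")
  consensus <- character(n); trace <- character(n)
  for (i in seq_len(n)) {
    if (ihc[i] == "missing") {
      consensus[i] <- nmc[i]
      trace[i] <- "ihc missing -> nmc"
      next
    }
    votes <- c(ihc[i], nmc[i])
    if (pam50[i] != "missing") votes <- c(votes, map_pam50_to_clinical(pam50[i]))
    tab <- table(votes)
    top <- names(tab)[tab >= 2]
    if (length(top) == 0L) {
      consensus[i] <- ihc[i]
      trace[i] <- "disagreement -> ihc"
    } else if (ihc[i] %in% top) {
      consensus[i] <- ihc[i]
      trace[i] <- sprintf("majority (%s)", paste(top, collapse = "/"))
    } else if (nmc[i] %in% top) {
      consensus[i] <- nmc[i]
      trace[i] <- sprintf("majority (%s)", paste(top, collapse = "/"))
    } else {
      consensus[i] <- ihc[i]
      trace[i] <- "no decisive majority -> ihc"
    }
  }
  data.frame(ihc = ihc, nmc = nmc, pam50 = pam50,
             consensus = consensus, vote_trace = trace,
             stringsAsFactors = FALSE)
}

#' Concordance between two call vectors
#'
#' Fraction of matching calls over jointly defined samples (both not
#' missing/NA). When `b_is_pam50 = TRUE`, a pair matches iff the clinical
#' subtype in `a` is compatible with the PAM50 label in `b`.
#'
#' @param a,b Character call vectors of equal length.
#' @param b_is_pam50 Interpret `b` through [map_pam50_to_clinical()].
#' @return Fraction in `[0, 1]`.
#' @export
concordance <- function(a, b, b_is_pam50 = FALSE) {
  ok <- !is.na(a) & !is.na(b) & a != "missing" & b != "missing"
  if (!any(ok)) format_error("concordance: no jointly defined samples")
  if (b_is_pam50) {
    match_i <- mapply(function(x, y) x %in% map_pam50_to_clinical(y), a[ok], b[ok])
  } else {
    match_i <- a[ok] == b[ok]
  }
  mean(match_i)
}
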