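## Virtual microdissection: KL-divergence NMF, exemplar genes, fraction
## normalisation, compartment attribution, CYT score.

kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Fit NMF by multiplicative updates minimising generalised KL divergence
#'
#' Factorises a non-negative expression matrix `V` (genes x samples, typically
#' `log2(TPM+1)`) as `V ~ W H` with `W >= 0` (genes x k) and `H >= 0`
#' (k x samples), using the multiplicative update rules for the generalised
#' Kullback-Leibler objective (the "brunet" scheme). `n_restarts` independent
#' random initialisations are run and the restart with the lowest final
#' objective is returned; the objective is non-increasing within each run.
#'
#' @param V Non-negative matrix; all-zero rows/columns are dropped with a
#'   warning.
#' @param k Factorisation rank, `k < min(dim(V))`.
#' @param n_restarts Number of random restarts (default 30).
#' @param seed Integer seed; restart `r` uses seed `seed + r`.
#' @param max_iter Maximum update iterations per restart (default 500).
#' @param tol Relative objective-change convergence tolerance, checked every
#'   10 iterations (default 1e-5).
#' @return Object of class `factor_model`: `W`, `H`, `k`, `objective`,
#'   `objective_trace` (best restart), `restart_objectives`, `seed`.
#' @export
nmf_fit <- function(V, k, n_restarts = 30L, seed = 1L, max_iter = 500L, tol = 1e-5) {
  if (any(V < 0)) format_error("nmf_fit: input matrix has negative entries")
  zr <- rowSums(V) == 0; zc <- colSums(V) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("nmf_fit: dropping %d all-zero row(s) and %d all-zero column(s)",
                    sum(zr), sum(zc)), call. = FALSE)
    V <- V[!zr, !zc, drop = FALSE]
  }
  if (k >= min(dim(V))) format_error("nmf_fit: k must be < min(genes, samples)")
  eps <- .Machine$double.eps
  best <- NULL
  restart_obj <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    res <- with_seed(derive_seed(seed, r), {
      W <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
      H <- matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V))
      trace <- numeric(0)
      prev <- Inf
      for (it in seq_len(max_iter)) {
        WH <- W %*% H + eps
        H <- H * (crossprod(W, V / WH)) / (colSums(W) + eps)
        WH <- W %*% H + eps
        W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps, each = nrow(W))
        if (it %% 10L == 0L || it == max_iter) {
          obj <- kl_divergence(V, W %*% H + eps)
          trace <- c(trace, obj)
          if (is.finite(prev) && abs(prev - obj) <= tol * max(abs(prev), 1)) break
          prev <- obj
        }
      }
      list(W = W, H = H, objective = trace[length(trace)], trace = trace)
    })
    restart_obj[r] <- res$objective
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  dimnames(best$W) <- list(rownames(V), paste0("F", seq_len(k)))
  dimnames(best$H) <- list(paste0("F", seq_len(k)), colnames(V))
  structure(list(W = best$W, H = best$H, k = k,
                 objective = best$objective, objective_trace = best$trace,
                 restart_objectives = restart_obj, seed = seed),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("NMF factor model: %d genes x %d samples, k = %d\n",
              nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  KL objective %.4g (best of %d restarts)\n",
              x$objective, length(x$restart_objectives)))
  if (!is.null(x$attribution)) {
    cat("  factor labels:\n")
    print(stats::setNames(x$attribution$label, x$attribution$factor))
  }
  invisible(x)
}

#' @export
summary.factor_model <- function(object, ...) {
  print(object)
  cat("  restart objectives:\n")
  print(summary(object$restart_objectives))
  invisible(object)
}

#' Entropy-based factor-specificity score of a gene
#'
#' For gene weights `w` over `k` factors with `p_j = w_j / sum(w)`, the score
#' is `1 + sum_j p_j log2 p_j / log2 k`: 1 for a gene loading on a single
#' factor, 0 for a gene spread uniformly over all factors.
#'
#' @param w Non-negative weight vector (one `W` row), sum > 0.
#' @return Score in `[0, 1]`.
#' @export
gene_score <- function(w) {
  s <- sum(w)
  if (s <= 0) return(NA_real_)
  p <- w / s
  p <- p[p > 0]
  1 + sum(p * log2(p)) / log2(length(w))
}

#' Extract exemplar genes of each factor
#'
#' A gene is an exemplar iff (1) its specificity score exceeds
#' `median(scores) + 3 * mad(scores)` and (2) its maximum factor contribution
#' exceeds the median of all entries of `W`. Each exemplar is assigned to its
#' argmax factor. Genes with all-zero weights are excluded.
#'
#' @param model A `factor_model`.
#' @return Data frame `gene`, `factor`, `score` (empty, with a warning, if no
#'   gene passes).
#' @export
extract_exemplars <- function(model) {
  W <- model$W
  ok <- rowSums(W) > 0
  scores <- apply(W[ok, , drop = FALSE], 1, gene_score)
  thr <- stats::median(scores) + 3 * stats::mad(scores)
  wmax <- apply(W[ok, , drop = FALSE], 1, max)
  pass <- scores > thr & wmax > stats::median(W)
  if (!any(pass)) {
    warning("no gene passes the exemplar criteria", call. = FALSE)
    return(data.frame(gene = character(), factor = character(), score = numeric()))
  }
  sel <- which(ok)[pass]
  data.frame(gene = rownames(W)[sel],
             factor = colnames(W)[apply(W[sel, , drop = FALSE], 1, which.max)],
             score = scores[pass],
             stringsAsFactors = FALSE)
}

#' Normalise factor weights to per-sample fractional contributions
#'
#' `W` columns are rescaled to sum to 1 (a diagonal matrix `S`) and `H` rows
#' inversely rescaled so the product `W H` is unchanged; then, over the
#' non-cohort factors only, each sample's `H` entries are renormalised to sum
#' to 1 as fractional compartment contributions.
#'
#' @param model A `factor_model`.
#' @param cohort_factors Character vector of cohort-specific factor names to
#'   exclude from the fractions (may be empty).
#' @return The model with `W_norm` (columns sum 1), `H_scaled` (product
#'   preserved), `fractions` (non-cohort factors x samples, columns sum 1)
#'   and `fractions_all` (all factors, for association analyses that must see
#'   the cohort-specific factors).
#' @export
normalize_fractions <- function(model, cohort_factors = character()) {
  s <- colSums(model$W)
  if (any(s == 0))
    format_error("normalize_fractions: factor %s has an all-zero W column",
                 colnames(model$W)[s == 0][1])
  model$W_norm <- sweep(model$W, 2, s, "/")
  model$H_scaled <- model$H * s
  keep <- setdiff(rownames(model$H_scaled), cohort_factors)
  Hk <- model$H_scaled[keep, , drop = FALSE]
  tot <- colSums(Hk)
  if (any(tot == 0))
    format_error("normalize_fractions: sample %s has zero total factor weight",
                 colnames(Hk)[tot == 0][1])
  model$fractions <- sweep(Hk, 2, tot, "/")
  ## fractions over every factor (cohort factors included): the correlation
  ## target for feature-to-compartment association, where cohort-specific
  ## factors must stay visible
  tot_all <- colSums(model$H_scaled)
  model$fractions_all <- sweep(model$H_scaled, 2, tot_all, "/")
  model$cohort_factors <- cohort_factors
  model
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of GZMA and PRF1 expression on the TPM scale, with a small
#' offset: `sqrt((GZMA + offset) * (PRF1 + offset))`.
#'
#' @param expr TPM expression matrix containing rows `GZMA` and `PRF1`.
#' @param offset Additive offset (default 0.01).
#' @return Named numeric vector, one score per sample.
#' @export
cyt_score <- function(expr, offset = 0.01) {
  for (g in c("GZMA", "PRF1")) if (!g %in% rownames(expr))
    format_error("cyt_score: gene %s absent from expression matrix", g)
  sqrt((expr["GZMA", ] + offset) * (expr["PRF1", ] + offset))
}

#' Attribute NMF factors to tissue compartments
#'
#' Codifies the manual attribution reasoning as an ordered rule engine applied
#' to group means of per-sample factor fractions (all factors). Groups are the
#' tumor cohort-by-subtype cells plus `adjacent_normal`, `healthy_normal` and
#' `cell_line`. Rules, in order:
#' 1. cohort-specific: one cohort's tumor mean is at least `ratio` times every
#'    other group mean (default ratio 2);
#' 2. adjacent/healthy normal: the respective normal group mean is the global
#'    maximum;
#' 3. TIL: tumor means exceed the adjacent-normal mean, which exceeds the
#'    cell-line mean, and the factor attains the maximal |r| with the CYT
#'    score (taken on the log scale, matching the log-space factor weights)
#'    among all factors, with that correlation at least `r_min`;
#' 4. tumor-intrinsic: the cell-line mean is at least the median of group
#'    means and the maximal group is a tumor subtype group (labelled with that
#'    subtype);
#' 5. stroma: every tumor cohort mean exceeds both normal-tissue group means
#'    and the cell-line mean is minimal;
#' 6. otherwise unassigned.
#' Every decision records the numeric comparisons used.
#'
#' @param model A `factor_model` (fractions are computed over all factors from
#'   `H` internally).
#' @param clinical Cohort table with `sample_id`, `cohort`, `group_label`.
#' @param subtype Named character vector of clinical subtypes for tumor (and
#'   cell-line) samples.
#' @param cyt Named numeric CYT score per sample (see [cyt_score()]).
#' @param ratio Cohort-specificity ratio (default 2).
#' @param r_min Minimum CYT correlation for the TIL rule (default 0.5).
#' @param min_tol Absolute tolerance when testing whether the cell-line mean
#'   is the minimal group mean (rule 5); fitted weights are never exactly
#'   zero, so a small slack (default 0.02) is allowed.
#' @return Data frame `factor`, `label`, `trace`; also attached to the model
#'   when assigned back.
#' @export
attribute_compartments <- function(model, clinical, subtype, cyt,
                                   ratio = 2, r_min = 0.5, min_tol = 0.02) {
  H <- model$H * colSums(model$W)     # scale-fixed weights
  frac <- sweep(H, 2, pmax(colSums(H), .Machine$double.eps), "/")
  cyt <- log2(cyt + 1)                # factor weights live on the log scale
  ids <- colnames(frac)
  cl <- clinical[match(ids, clinical$sample_id), ]
  if (anyNA(cl$sample_id))
    format_error("attribute_compartments: samples absent from clinical table")
  need <- c("tumor", "adjacent_normal", "healthy_normal", "cell_line")
  missing_lv <- setdiff(need, unique(cl$group_label))
  if (length(missing_lv))
    format_error("attribute_compartments: missing group label level '%s'", missing_lv[1])

  grp <- ifelse(cl$group_label == "tumor",
                paste0("tumor:", cl$cohort, ":", subtype[ids]),
                cl$group_label)
  group_means <- t(apply(frac, 1, function(v) tapply(v, grp, mean)))
  cohorts <- sort(unique(cl$cohort[cl$group_label == "tumor"]))
  tum_cohort_means <- vapply(cohorts, function(co)
    rowMeans(frac[, cl$group_label == "tumor" & cl$cohort == co, drop = FALSE]),
    numeric(nrow(frac)))
  cyt_r <- as.vector(stats::cor(t(frac), cyt[ids]))
  cyt_argmax <- which.max(abs(cyt_r))

  tumor_groups <- grep("^tumor:", colnames(group_means), value = TRUE)
  out <- data.frame(factor = rownames(frac), label = NA_character_,
                    trace = NA_character_, stringsAsFactors = FALSE)
  for (f in seq_len(nrow(frac))) {
    m <- group_means[f, ]
    adj <- m[["adjacent_normal"]]; hlt <- m[["healthy_normal"]]; cell <- m[["cell_line"]]
    label <- NULL; trace <- NULL
    ## rule 1: cohort-specific
    for (co in cohorts) {
      others <- c(tum_cohort_means[f, setdiff(cohorts, co)], adj, hlt, cell)
      if (tum_cohort_means[f, co] >= ratio * max(others)) {
        label <- paste0("cohort_specific:", co)
        trace <- sprintf("rule1: tumor[%s]=%.3f >= %g*max(others=%.3f)",
                         co, tum_cohort_means[f, co], ratio, max(others))
        break
      }
    }
    ## rule 2: normal-tissue factors
    if (is.null(label) && names(which.max(m)) == "adjacent_normal") {
      label <- "adjacent_normal"
      trace <- sprintf("rule2: adjacent mean %.3f is global max", adj)
    }
    if (is.null(label) && names(which.max(m)) == "healthy_normal") {
      label <- "healthy_normal"
      trace <- sprintf("rule2: healthy mean %.3f is global max", hlt)
    }
    ## rule 3: TIL
    if (is.null(label) && min(tum_cohort_means[f, ]) > adj && adj > cell &&
        f == cyt_argmax && cyt_r[f] >= r_min) {
      label <- "TIL"
      trace <- sprintf("rule3: tumors(min %.3f) > adjacent %.3f > cell %.3f; r(CYT)=%.2f max",
                       min(tum_cohort_means[f, ]), adj, cell, cyt_r[f])
    }
    ## rule 4: tumor-intrinsic
    if (is.null(label) && cell >= stats::median(m) &&
        names(which.max(m)) %in% tumor_groups) {
      st <- sub("^tumor:[^:]+:", "", names(which.max(m)))
      label <- paste0("tumor_intrinsic:", st)
      trace <- sprintf("rule4: cell %.3f >= median %.3f; max group %s",
                       cell, stats::median(m), names(which.max(m)))
    }
    ## rule 5: stroma
    if (is.null(label) && min(tum_cohort_means[f, ]) >= max(adj, hlt) &&
        cell <= min(m) + min_tol) {
      label <- "stroma"
      trace <- sprintf("rule5: tumors(min %.3f) >= normals(max %.3f); cell %.3f minimal",
                       min(tum_cohort_means[f, ]), max(adj, hlt), cell)
    }
    if (is.null(label)) {
      label <- "unassigned"
      trace <- sprintf("rule6: no rule matched (means: %s)",
                       paste(sprintf("%s=%.3f", names(m), m), collapse = ", "))
    }
    out$label[f] <- label
    out$trace[f] <- trace
  }
  out
}
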