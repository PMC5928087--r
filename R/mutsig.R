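## 96-channel substitution profiles and mutational-signature refitting.

#' The 96 trinucleotide substitution channels
#'
#' Channels are ordered lexicographically by pyrimidine-strand substitution
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank (A, C, G, T), then 3' flank,
#' and labelled in the conventional form `"A[C>A]A"`.
#'
#' @return Data frame with columns `label`, `ref`, `alt`, `five`, `three`.
#' @export
channel_table <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(three = BASES, five = BASES, sub = subs,
                      stringsAsFactors = FALSE)[, 3:1]
  ref <- substr(grid$sub, 1, 1)
  alt <- substr(grid$sub, 3, 3)
  data.frame(label = sprintf("%s[%s]%s", grid$five, grid$sub, grid$three),
             ref = ref, alt = alt, five = grid$five, three = grid$three,
             stringsAsFactors = FALSE)
}

#' A deterministic synthetic 30 x 96 signature catalog
#'
#' A stand-in catalog for tests and simulations: 30 row-stochastic signatures
#' over the 96 channels, each concentrated on a distinct set of dominant
#' channels so the refitting problem is well conditioned. It is synthetic —
#' generated from a fixed internal seed, identical on every call — and is not
#' the COSMIC catalog; real analyses should load the published catalog with
#' [read_signature_catalog()].
#'
#' @return Matrix 30 x 96, rownames `S1..S30`, colnames the channel labels,
#'   rows summing to 1.
#' @export
synthetic_signature_catalog <- function() {
  labels <- channel_table()$label
  with_seed(104729L, {
    cat30 <- matrix(stats::rgamma(30L * 96L, shape = 0.15, rate = 3), 30L, 96L)
    for (i in seq_len(30L)) {
      dom <- ((i - 1L) * 13L + (0:5) * 7L) %% 96L + 1L
      cat30[i, dom] <- cat30[i, dom] + c(8, 6, 5, 4, 3, 2)
    }
    cat30 <- cat30 / rowSums(cat30)
    dimnames(cat30) <- list(paste0("S", seq_len(30L)), labels)
    cat30
  })
}

#' Read a signature catalog TSV
#'
#' Dialect: 96 rows labelled by channel (`"A[C>A]A"`, first column) and one
#' column per signature. Rows are reordered to the canonical channel order and
#' the matrix is transposed to signatures x channels; signature rows must be
#' non-negative and are renormalised to sum to 1.
#'
#' @param path Path to TSV.
#' @return Matrix signatures x 96.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- channel_table()$label
  ids <- as.character(df[[1L]])
  if (!setequal(ids, labels))
    format_error("signature catalog '%s': first column must hold the 96 channel labels", path)
  m <- as.matrix(df[match(labels, ids), -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0)) format_error("signature catalog '%s': negative or missing entries", path)
  cat_m <- t(m)
  colnames(cat_m) <- labels
  cat_m / rowSums(cat_m)
}

#' Write a signature catalog TSV (channels x signatures)
#' @param catalog Matrix signatures x 96.
#' @param path Output path.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(channel = colnames(catalog), t(catalog), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build 96-channel mutation profiles
#'
#' Counts single-nucleotide substitutions per channel, reverse-complementing
#' purine-reference records to the pyrimidine convention. Non-SNV records are
#' ignored with a logged count; records whose trinucleotide context disagrees
#' with the reference base are listed and skipped. In `mode = "pooled"` all
#' member samples of each group are summed into one profile per group.
#'
#' @param muts Somatic mutation table (see [read_mutations()]).
#' @param mode `"sample"` (one profile per sample) or `"pooled"`.
#' @param groups For pooled mode, named character vector mapping `sample_id`
#'   to group.
#' @return Object of class `mutation_profile`: a 96 x n count matrix with
#'   attributes `skipped` (malformed records) and `n_non_snv`.
#' @export
build_profile <- function(muts, mode = c("sample", "pooled"), groups = NULL) {
  mode <- match.arg(mode)
  ch <- channel_table()
  snv <- nchar(muts$ref) == 1L & nchar(muts$alt) == 1L &
    muts$ref %in% BASES & muts$alt %in% BASES
  n_non_snv <- sum(!snv)
  if (n_non_snv > 0) message(n_non_snv, " non-SNV record(s) ignored")
  m <- muts[snv, , drop = FALSE]
  bad <- nchar(m$context) != 3L | substr(m$context, 2L, 2L) != m$ref
  skipped <- m[bad, , drop = FALSE]
  if (nrow(skipped) > 0)
    warning(sprintf("%d record(s) with context/ref mismatch skipped", nrow(skipped)),
            call. = FALSE)
  m <- m[!bad, , drop = FALSE]
  ## pyrimidine-strand normalisation
  pur <- m$ref %in% c("A", "G")
  if (any(pur)) {
    m$context[pur] <- unname(revcomp(m$context[pur]))
    m$ref[pur] <- chartr("ACGT", "TGCA", m$ref[pur])
    m$alt[pur] <- chartr("ACGT", "TGCA", m$alt[pur])
  }
  lab <- sprintf("%s[%s>%s]%s", substr(m$context, 1, 1), m$ref, m$alt,
                 substr(m$context, 3, 3))
  unit <- if (mode == "sample") m$sample_id else {
    if (is.null(groups)) format_error("build_profile: pooled mode needs 'groups'")
    unname(groups[m$sample_id])
  }
  units <- sort(unique(unit))
  prof <- matrix(0L, 96L, length(units), dimnames = list(ch$label, units))
  if (nrow(m) > 0) {
    tab <- table(factor(lab, levels = ch$label), factor(unit, levels = units))
    prof[] <- as.integer(tab)
  }
  structure(prof, class = c("mutation_profile", class(prof)),
            skipped = skipped, n_non_snv = n_non_snv)
}

#' Profile counts to frequencies
#' @param profile 96 x n count matrix.
#' @return Frequency matrix; all-zero columns become NA with a warning.
#' @export
profile_frequencies <- function(profile) {
  tot <- colSums(profile)
  if (any(tot == 0)) warning("profile with zero total: frequencies undefined", call. = FALSE)
  sweep(unclass(profile), 2, ifelse(tot > 0, tot, NA_real_), "/")
}

#' Refit signature exposures by constrained least squares
#'
#' Solves `min || f - sum_i w_i s_i ||^2` over `w >= 0` on the normalised
#' 96-channel frequency vector `f`, normalises `w` to sum 1, zeroes weights
#' below the prune threshold and renormalises. This is the refitting contract
#' of per-sample signature deconvolution: all 30 catalog signatures always
#' enter the fit (excluding similar signatures would overestimate the rest).
#'
#' @param profile A 96-vector of counts (or frequencies), or a 96 x n matrix —
#'   each column is fit independently.
#' @param catalog Signature catalog (signatures x 96).
#' @param prune Weights below this threshold are set to exactly 0 (default
#'   0.06) before renormalisation.
#' @return For a single profile, an object of class `signature_exposure`: list
#'   with `weights` (named, sums to 1), `residual` (L2 reconstruction error)
#'   and `n_mutations`. For a matrix, a list of such objects (one per column).
#' @export
refit_exposures <- function(profile, catalog, prune = 0.06) {
  if (is.matrix(profile) && ncol(profile) > 1L) {
    out <- lapply(seq_len(ncol(profile)), function(j)
      refit_exposures(profile[, j], catalog, prune))
    names(out) <- colnames(profile)
    return(out)
  }
  f <- as.vector(profile)
  if (length(f) != ncol(catalog)) format_error("refit_exposures: profile length != %d", ncol(catalog))
  tot <- sum(f)
  if (tot <= 0) format_error("refit_exposures: zero-total profile, exposures undefined")
  f <- f / tot
  S <- t(catalog)                       # 96 x n_sig
  w <- pracma::lsqnonneg(S, f)$x
  if (sum(w) <= 0) format_error("refit_exposures: degenerate fit (all-zero weights)")
  w <- w / sum(w)
  w[w < prune] <- 0
  w <- w / sum(w)
  names(w) <- rownames(catalog)
  structure(list(weights = w,
                 residual = sqrt(sum((f - as.vector(S %*% w))^2)),
                 n_mutations = tot),
            class = "signature_exposure")
}

#' @export
print.signature_exposure <- function(x, ...) {
  act <- x$weights[x$weights > 0]
  cat(sprintf("Signature exposure (%g mutations, residual %.4f)\n",
              x$n_mutations, x$residual))
  print(round(sort(act, decreasing = TRUE), 3))
  invisible(x)
}

#' Collect a list of exposures into a sample x signature matrix
#' @param exposures List of `signature_exposure` objects (named by sample).
#' @export
exposure_matrix <- function(exposures) {
  if (inherits(exposures, "signature_exposure")) exposures <- list(exposures)
  t(vapply(exposures, function(e) e$weights, numeric(length(exposures[[1]]$weights))))
}

#' Cohort prevalence filter on signature exposures
#'
#' A signature is retained iff the fraction of samples in which it is present
#' (weight > 0 after pruning) is at least `min_prevalence` in at least one
#' cohort; signatures below the threshold in both cohorts are removed and the
#' remaining weights renormalised per sample.
#'
#' @param expo Sample x signature weight matrix (rows sum to 1).
#' @param cohort Character vector of cohort labels aligned with rows.
#' @param min_prevalence Default 0.20 (strict `< 20%` removal).
#' @return List: `exposures` (filtered, renormalised), `retained` (signature
#'   names), `prevalence` (cohort x signature fraction matrix).
#' @export
prevalence_filter <- function(expo, cohort, min_prevalence = 0.2) {
  cohorts <- unique(cohort)
  if (length(cohorts) < 2L)
    warning("prevalence filter applied to a single cohort", call. = FALSE)
  prev <- t(vapply(cohorts, function(co)
    colMeans(expo[cohort == co, , drop = FALSE] > 0), numeric(ncol(expo))))
  rownames(prev) <- cohorts
  keep <- apply(prev >= min_prevalence, 2, any)
  out <- expo[, keep, drop = FALSE]
  rs <- rowSums(out)
  out[rs > 0, ] <- out[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(exposures = out, retained = colnames(expo)[keep], prevalence = prev)
}

#' Call homologous-recombination-deficiency status
#'
#' A sample is HRD-positive iff its signature-3 weight strictly exceeds the
#' threshold (default 0.2).
#'
#' @param exposure A `signature_exposure`, or a sample x signature matrix.
#' @param signature Name of the HRD signature column (default `"S3"`).
#' @param threshold Strict threshold, default 0.2.
#' @return Logical (vector for a matrix input).
#' @export
call_hrd <- function(exposure, signature = "S3", threshold = 0.2) {
  w <- if (inherits(exposure, "signature_exposure")) exposure$weights[signature]
       else exposure[, signature]
  unname(w > threshold)
}

#' Brute-force simplex-grid refitting oracle
#'
#' Independent check for [refit_exposures()]: enumerates all signature subsets
#' of size up to `max_active` and all weight compositions on a grid of the
#' given step, returning the grid point with minimal squared reconstruction
#' error. Exponential in `max_active`; intended for verification only.
#'
#' @param profile 96-vector of counts or frequencies.
#' @param catalog Signatures x 96 matrix.
#' @param step Grid step on the simplex (default 0.01).
#' @param max_active Maximum number of active signatures (default 3).
#' @return Named weight vector on the grid.
#' @export
grid_refit_oracle <- function(profile, catalog, step = 0.01, max_active = 3L) {
  f <- as.vector(profile); f <- f / sum(f)
  S <- t(catalog)
  G <- crossprod(S)                     # n_sig x n_sig
  b <- as.vector(crossprod(S, f))
  n_sig <- nrow(catalog)
  steps <- round(1 / step)
  ## compositions of `steps` into up to max_active parts (all positive)
  comp <- list()
  if (max_active >= 1L) comp[[1L]] <- matrix(steps, 1, 1)
  if (max_active >= 2L) {
    a <- seq_len(steps - 1L)
    comp[[2L]] <- cbind(a, steps - a)
  }
  if (max_active >= 3L) {
    cc <- expand.grid(a = seq_len(steps - 2L), b = seq_len(steps - 2L))
    cc <- cc[cc$a + cc$b <= steps - 1L, ]
    comp[[3L]] <- cbind(cc$a, cc$b, steps - cc$a - cc$b)
  }
  if (max_active > 3L) format_error("grid_refit_oracle: max_active > 3 not supported")
  best <- Inf; best_w <- NULL
  for (sz in seq_along(comp)) {
    grid <- comp[[sz]] * step                     # n_grid x sz
    subsets <- utils::combn(n_sig, sz)
    for (ci in seq_len(ncol(subsets))) {
      ss <- subsets[, ci]
      Gs <- G[ss, ss, drop = FALSE]
      bs <- b[ss]
      ## residual^2 (up to the constant f'f) = w'Gw - 2 w'b
      q <- rowSums((grid %*% Gs) * grid) - 2 * as.vector(grid %*% bs)
      j <- which.min(q)
      if (q[j] < best) {
        best <- q[j]
        best_w <- numeric(n_sig)
        best_w[ss] <- grid[j, ]
      }
    }
  }
  names(best_w) <- rownames(catalog)
  best_w
}
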