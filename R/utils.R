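#' Solve the linear assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix via the shortest
#' augmenting path (Hungarian) algorithm, O(n^3). Used to match fitted NMF
#' factors to planted ground-truth factors.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `perm` with `perm[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost), all(is.finite(cost)))
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row currently assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j]] <- j
  perm
}

#' Match fitted factors to reference factors by correlation
#'
#' Computes Pearson correlations between rows of two factor-by-sample weight
#' matrices and solves the assignment maximising total |r|.
#'
#' @param H_fit,H_ref Factor x sample matrices with equal sample columns.
#' @return List with `pairs` (data.frame fit, ref, r) and `min_abs_r`.
#' @export
match_factors <- function(H_fit, H_ref) {
  stopifnot(ncol(H_fit) == ncol(H_ref))
  r <- stats::cor(t(H_fit), t(H_ref))
  r[!is.finite(r)] <- 0
  k <- max(nrow(H_fit), nrow(H_ref))
  cost <- matrix(1, k, k)  # pad non-square with worst cost
  cost[seq_len(nrow(H_fit)), seq_len(nrow(H_ref))] <- 1 - abs(r)
  perm <- solve_assignment(cost)
  fit_idx <- seq_len(nrow(H_fit))
  ref_idx <- perm[fit_idx]
  keep <- ref_idx <= nrow(H_ref)
  pairs <- data.frame(fit = fit_idx[keep], ref = ref_idx[keep],
                      r = r[cbind(fit_idx[keep], ref_idx[keep])])
  list(pairs = pairs, min_abs_r = min(abs(pairs$r)))
}

## Run code under a derived, restorable RNG state. `offset` keeps derived seeds
## well below 2^31 for any small user seed.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
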