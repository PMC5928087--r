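test_that("assignment solver matches brute-force enumeration", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  }
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(2:6, 1)
    cm <- matrix(runif(n * n), n)
    perm <- solve_assignment(cm)
    expect_true(all(sort(perm) == seq_len(n)))
    best <- min(vapply(perms(seq_len(n)),
                       function(p) sum(cm[cbind(seq_len(n), p)]), 0))
    expect_equal(sum(cm[cbind(seq_len(n), perm)]), best)
  }
})

test_that("NMF attains a near-exact fit in the noiseless limit", {
  set.seed(32)
  W0 <- matrix(rexp(50 * 3), 50, 3)
  H0 <- matrix(rexp(3 * 30), 3, 30)
  V <- W0 %*% H0
  dimnames(V) <- list(paste0("g", 1:50), paste0("s", 1:30))
  fit <- nmf_fit(V, k = 3, n_restarts = 5, seed = 1, max_iter = 2000, tol = 1e-10)
  expect_lt(fit$objective, 1e-6 * sum(V))
  expect_true(all(diff(fit$objective_trace) <= 1e-8))   # non-increasing
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_error(nmf_fit(-V, 2), "negative")
})

test_that("all-zero rows are dropped with a warning", {
  set.seed(33)
  V <- matrix(rexp(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  V[3, ] <- 0
  expect_warning(fit <- nmf_fit(V, k = 2, n_restarts = 2, seed = 1), "all-zero")
  expect_equal(nrow(fit$W), 19)
})

test_that("gene scores follow the entropy closed forms", {
  expect_equal(gene_score(c(5, 0, 0, 0)), 1)
  expect_equal(gene_score(rep(2, 8)), 0)
  expect_equal(gene_score(c(1, 1, 0, 0)), 0.5)   # 1 + (1/2)(-1)
  expect_true(is.na(gene_score(c(0, 0, 0))))
})

test_that("exemplar extraction selects planted one-hot markers exactly", {
  set.seed(34)
  W <- matrix(runif(110 * 4, 0.5, 1.5), 110, 4)
  W[1:10, ] <- 0
  for (i in 1:10) W[i, (i %% 4) + 1] <- 10
  dimnames(W) <- list(paste0("g", 1:110), paste0("F", 1:4))
  model <- structure(list(W = W, H = matrix(1, 4, 5), k = 4), class = "factor_model")
  ex <- extract_exemplars(model)
  expect_setequal(ex$gene, paste0("g", 1:10))
  expect_equal(ex$factor, paste0("F", (1:10 %% 4) + 1))

  W2 <- matrix(1, 50, 4, dimnames = list(paste0("g", 1:50), paste0("F", 1:4)))
  model2 <- structure(list(W = W2, H = matrix(1, 4, 5), k = 4), class = "factor_model")
  expect_warning(ex2 <- extract_exemplars(model2), "no gene")
  expect_equal(nrow(ex2), 0)
})

test_that("fraction normalisation preserves the product and sums to 1", {
  set.seed(35)
  W <- matrix(rexp(40 * 4), 40, 4, dimnames = list(paste0("g", 1:40), paste0("F", 1:4)))
  H <- matrix(rexp(4 * 12), 4, 12, dimnames = list(paste0("F", 1:4), paste0("s", 1:12)))
  model <- structure(list(W = W, H = H, k = 4), class = "factor_model")
  out <- normalize_fractions(model, cohort_factors = "F4")
  expect_equal(out$W_norm %*% out$H_scaled, W %*% H, tolerance = 1e-10)
  expect_equal(colSums(out$W_norm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(colSums(out$fractions), rep(1, 12), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(rownames(out$fractions), c("F1", "F2", "F3"))
  expect_equal(colSums(out$fractions_all), rep(1, 12), ignore_attr = TRUE)

  one <- structure(list(W = W[, 1, drop = FALSE], H = H[1, , drop = FALSE], k = 1),
                   class = "factor_model")
  out1 <- normalize_fractions(one)
  expect_equal(unname(out1$fractions[1, ]), rep(1, 12))
  W0 <- W; W0[, 2] <- 0
  expect_error(normalize_fractions(structure(list(W = W0, H = H, k = 4),
                                             class = "factor_model")), "F2")
})

test_that("CYT score is the offset geometric mean of GZMA and PRF1", {
  expr <- rbind(GZMA = c(4, 0), PRF1 = c(9, 0))
  colnames(expr) <- c("s1", "s2")
  expect_equal(unname(cyt_score(expr, offset = 0)), c(6, 0))
  expect_equal(unname(cyt_score(expr)["s2"]), 0.01)
  expect_equal(cyt_score(expr[, 2:1]), cyt_score(expr)[2:1])  # order-invariant
  expect_error(cyt_score(expr[1, , drop = FALSE]), "PRF1")
})

test_that("attribution is a total function with informative traces", {
  fx <- full_fixture()
  att <- fx$model$attribution
  expect_equal(nrow(att), fx$model$k)
  expect_true(all(!is.na(att$label)))
  expect_true(all(nzchar(att$trace)))
  ## forced cohort-specific factor: weight only in cohort A tumors
  comp <- fx$comp
  H <- fx$model$H
  cl <- comp$clinical
  Hf <- rbind(H, forced = as.numeric(cl$group_label == "tumor" & cl$cohort == "A"))
  Wf <- cbind(fx$model$W, forced = rep(1, nrow(fx$model$W)))
  mf <- structure(list(W = Wf, H = Hf, k = nrow(Hf)), class = "factor_model")
  attf <- attribute_compartments(mf, cl, comp$truth$subtype, fx$cyt)
  expect_equal(attf$label[attf$factor == "forced"], "cohort_specific:A")
})
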