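make_mut <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], gene = "G", chrom = "1", pos = 1L,
               ref = r[[2]], alt = r[[3]], context = r[[4]],
               protein_altering = FALSE, stringsAsFactors = FALSE)))
}

test_that("profiles count channels with pyrimidine normalisation", {
  m <- make_mut(list("s1", "C", "T", "ACA"))
  p <- build_profile(m)
  expect_equal(sum(p), 1)
  expect_equal(unclass(p)["A[C>T]A", "s1"], 1)

  ## purine-strand record G>A with context TGT is the same event as A[C>T]A
  m2 <- make_mut(list("s1", "G", "A", "TGT"))
  p2 <- build_profile(m2)
  expect_equal(unclass(p2)["A[C>T]A", "s1"], 1)

  ## malformed context is skipped with a warning; non-SNV silently counted
  m3 <- rbind(make_mut(list("s1", "C", "T", "AAA"), list("s1", "C", "T", "ACA")),
              data.frame(sample_id = "s1", gene = "G", chrom = "1", pos = 9L,
                         ref = "CT", alt = "C", context = "NCT",
                         protein_altering = FALSE))
  expect_warning(p3 <- build_profile(m3), "mismatch")
  expect_equal(sum(p3), 1)
  expect_equal(nrow(attr(p3, "skipped")), 1)
})

test_that("empty catalogs give all-zero profiles with undefined frequencies", {
  m <- make_mut(list("s1", "C", "T", "ACA"))[0, ]
  m$sample_id <- character(0)
  p <- build_profile(rbind(m, make_mut(list("s2", "C", "T", "ACA"))))
  expect_equal(dim(p), c(96L, 1L))
  p0 <- unclass(p); p0[] <- 0L
  expect_warning(fr <- profile_frequencies(p0), "zero total")
  expect_true(all(is.na(fr)))
})

test_that("pooled profiles equal the sum of member samples", {
  m <- rbind(make_mut(list("s1", "C", "T", "ACA"), list("s2", "C", "T", "ACA"),
                      list("s2", "T", "G", "GTC")))
  pooled <- build_profile(m, mode = "pooled", groups = c(s1 = "g", s2 = "g"))
  per <- build_profile(m, mode = "sample")
  expect_equal(unclass(pooled)[, "g"], rowSums(unclass(per)))
})

test_that("refitting recovers exact catalog members and mixtures", {
  catal <- synthetic_signature_catalog()
  expect_equal(dim(catal), c(30L, 96L))
  expect_equal(rowSums(catal), rep(1, 30), ignore_attr = TRUE)
  expect_identical(catal, synthetic_signature_catalog())  # deterministic

  e1 <- refit_exposures(catal["S1", ] * 1e4, catal)
  expect_equal(unname(e1$weights["S1"]), 1)
  expect_equal(sum(e1$weights), 1, tolerance = 1e-9)

  f <- 0.5 * catal["S1", ] + 0.5 * catal["S3", ]
  e2 <- refit_exposures(f, catal, prune = 0)
  expect_equal(unname(e2$weights[c("S1", "S3")]), c(0.5, 0.5), tolerance = 1e-6)
  expect_lt(e2$residual, 1e-9)
  expect_error(refit_exposures(rep(0, 96), catal), "zero-total")
})

test_that("multinomial sampling recovers template exposures within 0.05", {
  catal <- synthetic_signature_catalog()
  truth <- c(S1 = 0.6, S3 = 0.3, S13 = 0.1)
  p <- as.vector(truth %*% catal[names(truth), ])
  set.seed(21)
  err <- replicate(20, {
    cnt <- as.vector(rmultinom(1, 2000, p))
    e <- refit_exposures(cnt, catal)
    abs(e$weights[names(truth)] - truth)
  })
  expect_lt(mean(err), 0.05)
})

test_that("refitting agrees with the simplex-grid oracle", {
  catal <- synthetic_signature_catalog()
  cases <- list(c(S2 = 0.7, S5 = 0.3),
                c(S1 = 0.5, S3 = 0.3, S13 = 0.2))
  for (truth in cases) {
    f <- as.vector(truth %*% catal[names(truth), ])
    w_fit <- refit_exposures(f, catal, prune = 0)$weights
    w_oracle <- grid_refit_oracle(f, catal)
    expect_lt(max(abs(w_fit - w_oracle)), 0.02)
  }
})

test_that("pooling identical samples preserves the exposure", {
  catal <- synthetic_signature_catalog()
  f <- 0.6 * catal["S1", ] + 0.4 * catal["S3", ]
  cnt <- round(f * 5000)
  m1 <- refit_exposures(cnt, catal)
  m2 <- refit_exposures(cnt * 3, catal)   # three identical samples pooled
  expect_equal(m1$weights, m2$weights, tolerance = 1e-12)
})

test_that("prevalence filter applies the 20% rule per cohort", {
  expo <- matrix(0, 20, 3, dimnames = list(NULL, c("S1", "S2", "S3")))
  expo[, "S1"] <- 0.8
  cohort <- rep(c("A", "B"), each = 10)
  expo[1:3, "S2"] <- 0.2                      # 30% of A, 0% of B -> retained
  expo[c(1, 11), "S3"] <- 0.1                 # 10% of A, 10% of B -> removed
  expo[, 1] <- 1 - rowSums(expo[, 2:3, drop = FALSE])
  out <- prevalence_filter(expo, cohort)
  expect_setequal(out$retained, c("S1", "S2"))
  expect_equal(rowSums(out$exposures), rep(1, 20))

  ## boundary: 19% in both cohorts (strict < 20% removal), 100 samples/cohort
  expo2 <- matrix(0, 200, 2, dimnames = list(NULL, c("S1", "S2")))
  cohort2 <- rep(c("A", "B"), each = 100)
  expo2[c(1:19, 101:119), "S2"] <- 0.5
  expo2[, "S1"] <- 1 - expo2[, "S2"]
  out2 <- prevalence_filter(expo2, cohort2)
  expect_equal(out2$retained, "S1")
  ## at exactly 20% the signature is retained
  expo2[c(1:20), "S2"] <- 0.5; expo2[, "S1"] <- 1 - expo2[, "S2"]
  expect_setequal(prevalence_filter(expo2, cohort2)$retained, c("S1", "S2"))
  expect_warning(prevalence_filter(expo2[1:100, ], cohort2[1:100]), "single cohort")
})

test_that("HRD calling uses a strict S3 > 0.2 threshold", {
  w <- matrix(c(0.25, 0.20, 0), 3, 1, dimnames = list(NULL, "S3"))
  expect_equal(call_hrd(w), c(TRUE, FALSE, FALSE))
})

test_that("catalog TSV round-trips through read/write", {
  catal <- synthetic_signature_catalog()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_signature_catalog(catal, p)
  back <- read_signature_catalog(p)
  expect_equal(back, catal, tolerance = 1e-12)
})

test_that("simulated TNBC samples carry more HRD signal than ER+ samples", {
  fx <- full_fixture()
  comp <- fx$comp
  catal <- synthetic_signature_catalog()
  mut <- simulate_mutation_catalogs(comp$truth$config, comp$clinical, comp$truth, catal)
  prof <- build_profile(mut$mutations, mode = "sample")
  keep <- colSums(prof) > 0
  expos <- refit_exposures(unclass(prof)[, keep, drop = FALSE], catal)
  emat <- exposure_matrix(expos)
  st <- comp$truth$subtype[rownames(emat)]
  expect_gt(mean(emat[st == "TN", "S3"]), mean(emat[st == "ER+", "S3"]))
  expect_gt(mean(call_hrd(emat[st == "TN", , drop = FALSE])), 0.5)
})
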