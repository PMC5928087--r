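test_that("gene filter removes low-mean then low-variance quartiles", {
  set.seed(41)
  expr <- matrix(rnorm(100 * 10, mean = rep(1:100, 10)), 100, 10,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:10)))
  out <- filter_genes(expr)
  expect_equal(nrow(out), 57)   # 100 -> 75 -> 75 - floor(18.75)
  ## constant-zero genes are always removed first
  expr[1:20, ] <- 0
  expect_false(any(rownames(filter_genes(expr)) %in% sprintf("g%03d", 1:20)))

  ## ties broken lexicographically: 8 identical genes, mean filter removes
  ## the first floor(0.25*8) = 2 by gene id
  e8 <- matrix(1, 8, 4, dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
  e8 <- e8 + matrix(rep(c(0, .1, 0, .1), each = 8), 8, 4)   # equal mean and sd
  out8 <- filter_genes(e8)
  expect_false(any(c("g1", "g2") %in% rownames(out8)))
  expect_error(filter_genes(e8[1:4, ]), ">= 8")
})

test_that("DE test is calibrated under the null and adjusts for purity", {
  set.seed(42)
  mat <- matrix(rnorm(50 * 60), 50, 60,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:60)))
  group <- rep(c("A", "B"), each = 30)
  de <- de_test(mat, group)
  expect_true(all(abs(de$effect) < 1))
  expect_false(any(de$pass))
  expect_gt(min(de$fdr), 0.2)
  ## BH FDR is monotone in p
  o <- order(de$p)
  expect_true(all(diff(cummin(rev(de$fdr[o]))) <= 0) || all(diff(de$fdr[o]) >= -1e-12))

  ## purity-driven artifact: expression tracks purity, purity differs by group
  purity <- c(rnorm(30, 0.5, 0.05), rnorm(30, 0.8, 0.05))
  art <- matrix(rep(4 * purity, each = 2) + rnorm(120, 0, 0.05), 2, 60,
                dimnames = list(c("art1", "art2"), colnames(mat)))
  de_no <- de_test(art, group)
  de_adj <- de_test(art, group, covariates = data.frame(purity = purity))
  expect_true(all(de_no$p < 1e-6))
  expect_true(all(de_adj$p > 0.01))
})

test_that("planted fold changes are recovered at the stated thresholds", {
  set.seed(43)
  n <- 40
  mat <- matrix(rnorm(200 * 2 * n, mean = 5, sd = 0.7), 200, 2 * n,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:(2 * n))))
  group <- rep(c("A", "B"), each = n)
  mat[1:50, group == "B"] <- mat[1:50, group == "B"] + 2    # 4-fold shift
  de <- de_test(mat, group)
  recall <- mean(de$pass[1:50])
  expect_gte(recall, 0.9)
  expect_lt(mean(de$pass[51:200]), 0.05)
  expect_equal(median(de$effect[1:50]), 2, tolerance = 0.2)
})

test_that("collinear covariates are dropped deterministically", {
  set.seed(44)
  mat <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  group <- rep(c("A", "B"), each = 15)
  cov <- data.frame(x1 = rnorm(30))
  cov$x2 <- 2 * cov$x1
  expect_warning(de <- de_test(mat, group, cov), "collinear")
  expect_equal(nrow(de), 10)
})

test_that("pathway scores behave at the rank extremes", {
  set.seed(45)
  expr <- matrix(rexp(30 * 8), 30, 8,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  sets <- list(all = rownames(expr), top = "g1")
  expr["g1", ] <- 100                        # top-expressed everywhere
  sc <- score_pathways(expr, sets)
  expect_equal(unname(sc["all", ]), rep(0, 8), tolerance = 1e-12)
  expect_true(all(sc["top", ] >= apply(sc, 2, max) - 1e-12))
  expect_warning(score_pathways(expr, list(gone = c("nope1", "nope2"))), "no expressed")

  ## a coordinated up-shift puts that pathway on top of the DE list
  g <- rep(c("A", "B"), each = 10)
  e2 <- matrix(rnorm(40 * 20, 5), 40, 20,
               dimnames = list(paste0("g", 1:40), paste0("s", 1:20)))
  e2[1:8, g == "A"] <- e2[1:8, g == "A"] + 3
  sets2 <- list(up = paste0("g", 1:8), bg1 = paste0("g", 9:20), bg2 = paste0("g", 21:40))
  sc2 <- score_pathways(e2, sets2)
  de2 <- de_test(sc2, g, feature_type = "pathway")
  expect_equal(de2$feature[which.min(de2$p)], "up")
  expect_true(de2$pass[de2$feature == "up"])
})

test_that("feature-factor association finds exact and inverted matches", {
  set.seed(46)
  H <- matrix(rexp(4 * 50), 4, 50,
              dimnames = list(paste0("F", 1:4), paste0("s", 1:50)))
  feats <- rbind(hit = H[2, ], anti = -H[3, ],
                 noise = rnorm(50), flat = rep(1, 50))
  colnames(feats) <- colnames(H)
  expect_warning(a <- associate_features(feats, H, n_perm = 20, seed = 1),
                 "zero-variance")
  expect_equal(a$max_r[a$feature == "hit"], 1, tolerance = 1e-12)
  expect_equal(a$argmax_factor[a$feature == "hit"], "F2")
  expect_true(a$associated[a$feature == "hit"])
  expect_equal(a$p[a$feature == "hit"], min(a$p, na.rm = TRUE))
  ## signed max ignores the perfect anti-correlation; absolute mode finds it
  r <- attr(a, "r_matrix")
  expect_equal(unname(r["anti", "F3"]), -1, tolerance = 1e-12)
  expect_lt(a$max_r[a$feature == "anti"], 1)
  ab <- suppressWarnings(associate_features(feats, H, n_perm = 20, seed = 1,
                                            mode = "absolute"))
  expect_equal(ab$max_r[ab$feature == "anti"], 1, tolerance = 1e-12)
  expect_equal(ab$argmax_factor[ab$feature == "anti"], "F3")
  expect_true(is.na(a$max_r[a$feature == "flat"]))
  expect_false(a$associated[a$feature == "flat"])
})

test_that("permutation p converges to the analytic max-correlation p", {
  set.seed(47)
  n <- 40; k <- 3
  Ho <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  H <- t(Ho); dimnames(H) <- list(paste0("F", 1:k), paste0("s", 1:n))
  feats <- matrix(rnorm(200 * n), 200, n,
                  dimnames = list(paste0("g", 1:200), colnames(H)))
  a <- associate_features(feats, H, n_perm = 1000, seed = 2)
  p_one <- function(v) ifelse(v >= 0,
    1 - stats::pbeta(v^2, 1 / 2, (n - 2) / 2, lower.tail = FALSE) / 2,
    stats::pbeta(v^2, 1 / 2, (n - 2) / 2, lower.tail = FALSE) / 2)
  p_analytic <- 1 - p_one(a$max_r)^k
  expect_lt(mean(abs(a$p - p_analytic)), 0.01)
  expect_lt(max(abs(a$p - p_analytic)), 0.05)
})

test_that("categorisation applies the 0.2 margins on class maxima", {
  r <- rbind(tumorish = c(0.9, 0.3, 0.1),
             close = c(0.5, 0.45, 0.2),
             cohortish = c(0.1, 0.1, 0.8),
             tmeish = c(0.1, 0.6, 0.15))
  colnames(r) <- c("F1", "F2", "F3")
  a <- data.frame(feature = rownames(r), max_r = apply(r, 1, max),
                  argmax_factor = colnames(r)[apply(r, 1, which.max)],
                  p = 0.01, fdr = 0.01, associated = TRUE)
  attr(a, "r_matrix") <- r
  attr(a, "mode") <- "signed"
  labels <- c(F1 = "tumor_intrinsic:ER+", F2 = "TIL", F3 = "cohort_specific:A")
  out <- categorize(a, labels)
  expect_equal(out$category,
               c("tumor_intrinsic", "ambiguous", "cohort_specific", "TME"))
  expect_error(categorize(a, labels[1:2]), "unlabeled")
  ## categories partition all categorised features
  expect_true(all(out$category %in%
                  c("tumor_intrinsic", "TME", "cohort_specific", "ambiguous")))
})
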