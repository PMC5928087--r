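## Synthetic multi-cohort compendium generator.
##
## The generator plants, in log2(TPM+1) space, a non-negative factor structure
## V = W.H with factor-exclusive marker-gene blocks, so that every downstream
## stage (NMF dissection, subtype calling, DE attribution) has a known ground
## truth to be measured against. Noise is multiplicative lognormal on TPM.

#' Default simulation configuration
#'
#' Returns the configuration of the synthetic compendium: a four-group design
#' (two tumor cohorts A and B with different subtype mixes, adjacent-normal
#' tissue, healthy tissue, cell lines), planted expression factors (one
#' tumor-intrinsic factor per clinical subtype, a TIL factor enriched in cohort
#' A, a stroma factor absent from cell lines, healthy- and adjacent-tissue
#' factors, and one batch factor per tumor cohort), subtype-specific mutation
#' signature exposure templates (TNBC weighted to the HRD signature S3, HER2+
#' subtypes to APOBEC signatures S2/S13), an age-increasing mutation burden,
#' age-enriched germline carriers concentrated in cohort A, and ERBB2
#' amplification concentrated in HER2-positive samples.
#'
#' @param seed Integer seed controlling every random draw.
#' @param ... Named overrides of any default field.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_tumor_A = 120L, n_tumor_B = 120L,
    n_adjacent = 20L, n_healthy = 20L, n_cell_line = 20L,
    subtype_mix = list(
      A = c("ER+" = 0.54, "ER+/HER2+" = 0.16, "HER2+" = 0.10, "TN" = 0.20),
      B = c("ER+" = 0.79, "ER+/HER2+" = 0.06, "HER2+" = 0.03, "TN" = 0.12)),
    markers_per_factor = 25L,
    n_background_genes = 550L,
    noise_sd = 0.3,
    marker_weight_range = c(4, 7),
    til_mean = c(A = 0.70, B = 0.40),
    stroma_mean = 0.55,
    adjacent_til = 0.18,
    de_tumor_genes_per_factor = 6L,
    de_tumor_log2fc = 2,
    exposure_templates = list(
      "ER+"       = c(S1 = 0.55, S5 = 0.30, S2 = 0.10, S13 = 0.05),
      "ER+/HER2+" = c(S1 = 0.30, S2 = 0.30, S13 = 0.25, S5 = 0.15),
      "HER2+"     = c(S1 = 0.25, S2 = 0.35, S13 = 0.30, S5 = 0.10),
      "TN"        = c(S1 = 0.15, S3 = 0.65, S5 = 0.10, S13 = 0.10)),
    burden_base = 120, burden_age_slope = 0.015,
    germline_rate = c(A = 0.12, B = 0.045),
    germline_age_coef = 0.06,
    erbb2_leakage = 0.02,
    age_mean = c(A = 40, B = 58), age_sd = c(A = 8.5, B = 13.2)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    format_error("sim_config: unknown field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_tumor_A, cfg$n_tumor_B, cfg$n_adjacent, cfg$n_healthy, cfg$n_cell_line)
  if (any(counts < 1L)) format_error("sim_config: all group sizes must be >= 1")
  for (co in names(cfg$subtype_mix)) {
    s <- sum(cfg$subtype_mix[[co]])
    if (abs(s - 1) > 1e-8)
      format_error("sim_config: subtype mix for cohort %s sums to %g, not 1", co, s)
  }
  for (st in names(cfg$exposure_templates)) {
    s <- sum(cfg$exposure_templates[[st]])
    if (abs(s - 1) > 1e-8)
      format_error("sim_config: exposure template for %s sums to %g, not 1", st, s)
  }
  if (cfg$noise_sd < 0) format_error("sim_config: noise_sd must be >= 0")
  invisible(cfg)
}

sim_factor_names <- c("tumor_ER", "tumor_ERHER2", "tumor_HER2", "tumor_TNBC",
                      "TIL", "stroma", "healthy", "adjacent", "batch_A", "batch_B")

sim_factor_labels <- c(
  tumor_ER = "tumor_intrinsic:ER+", tumor_ERHER2 = "tumor_intrinsic:ER+/HER2+",
  tumor_HER2 = "tumor_intrinsic:HER2+", tumor_TNBC = "tumor_intrinsic:TN",
  TIL = "TIL", stroma = "stroma", healthy = "healthy_normal",
  adjacent = "adjacent_normal", batch_A = "cohort_specific:A",
  batch_B = "cohort_specific:B")

subtype_to_factor <- c("ER+" = "tumor_ER", "ER+/HER2+" = "tumor_ERHER2",
                       "HER2+" = "tumor_HER2", "TN" = "tumor_TNBC")

## Gamma draw with given mean and shape (sd = mean/sqrt(shape)); mean 0 -> 0.
rgamma_mean <- function(n, mean, shape = 8) {
  if (mean <= 0) return(rep(0, n))
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulate the expression compendium and clinical table
#'
#' Generates log-space expression `V = W.H` from factor-exclusive marker
#' blocks, exponentiates to TPM and applies multiplicative lognormal noise.
#' Cohort A is younger and pre-menopausal-enriched; its TIL factor mean exceeds
#' cohort B's, so TIL marker genes are the planted TME-origin differentially
#' expressed genes; a small set of tumor-factor markers additionally receives a
#' log2 fold-change in cohort A tumors, forming the planted tumor-intrinsic DE
#' genes. GZMA and PRF1 are planted TIL markers so the cytolytic (CYT) score
#' tracks the TIL factor; ESR1/PGR/ERBB2 load on the matching receptor-defined
#' tumor factors for the mixture-model subtype classifier.
#'
#' @param cfg A [sim_config()].
#' @return List of class `bc_compendium` with elements `expression` (TPM
#'   matrix), `clinical` (cohort table) and `truth` (planted ground truth:
#'   `H_true`, `fractions_true`, `W_true`, per-sample `subtype`, factor labels,
#'   marker lists and DE gene lists).
#' @export
simulate_compendium <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 1L))
  k <- length(sim_factor_names)

  ## ---- samples and clinical covariates
  n_T <- c(A = cfg$n_tumor_A, B = cfg$n_tumor_B)
  tum_ids <- c(sprintf("A_T%03d", seq_len(n_T["A"])), sprintf("B_T%03d", seq_len(n_T["B"])))
  tum_cohort <- rep(c("A", "B"), n_T)
  adj_ids <- sprintf("%s_N%02d", rep(c("A", "B"), length.out = cfg$n_adjacent),
                     seq_len(cfg$n_adjacent))
  adj_cohort <- rep(c("A", "B"), length.out = cfg$n_adjacent)
  hlt_ids <- sprintf("H_N%02d", seq_len(cfg$n_healthy))
  cl_ids <- sprintf("CL%02d", seq_len(cfg$n_cell_line))
  ids <- c(tum_ids, adj_ids, hlt_ids, cl_ids)
  n <- length(ids)

  subtypes <- names(subtype_to_factor)
  tum_subtype <- unlist(lapply(c("A", "B"), function(co) {
    sample(subtypes, n_T[co], replace = TRUE, prob = cfg$subtype_mix[[co]])
  }))
  cl_subtype <- rep(subtypes, length.out = cfg$n_cell_line)
  subtype <- c(tum_subtype, rep(NA_character_, cfg$n_adjacent + cfg$n_healthy), cl_subtype)
  names(subtype) <- ids

  age <- c(stats::rnorm(n_T["A"], cfg$age_mean["A"], cfg$age_sd["A"]),
           stats::rnorm(n_T["B"], cfg$age_mean["B"], cfg$age_sd["B"]),
           stats::rnorm(cfg$n_adjacent + cfg$n_healthy, 50, 10),
           rep(NA_real_, cfg$n_cell_line))
  age[!is.na(age)] <- pmin(pmax(age[!is.na(age)], 22), 88)
  meno <- ifelse(is.na(age), "missing",
                 ifelse(stats::runif(n) < stats::plogis((50 - age) / 2), "pre", "post"))
  meno[stats::runif(n) < 0.04 & meno != "missing"] <- "peri"
  meno[ids %in% cl_ids] <- "missing"

  purity <- rep(NA_real_, n)
  purity[seq_along(tum_ids)] <- c(stats::rbeta(n_T["A"], 3.9, 1.6),
                                  stats::rbeta(n_T["B"], 11, 3.2))
  purity[ids %in% cl_ids] <- 1

  histology <- rep("missing", n)
  histology[seq_along(tum_ids)] <- c(
    sample(c("ductal", "lobular", "other"), n_T["A"], TRUE, c(0.92, 0.04, 0.04)),
    sample(c("ductal", "lobular", "other"), n_T["B"], TRUE, c(0.77, 0.18, 0.05)))
  stage <- rep("missing", n)
  stage[seq_along(tum_ids)] <- sample(c("I", "II", "III", "IV"), length(tum_ids), TRUE,
                                      c(0.15, 0.54, 0.27, 0.04))

  is_tumor <- seq_len(n) <= length(tum_ids)
  fh_p <- rep(0, n)
  fh_p[is_tumor] <- ifelse(tum_cohort == "A",
                           ifelse(age[is_tumor] <= 40, 0.24, 0.08),
                           ifelse(age[is_tumor] <= 40, 0.10, 0.05))
  family_history <- ifelse(is_tumor, ifelse(stats::runif(n) < fh_p, "yes", "no"), "missing")

  ## IHC calls: derived from true subtype with a small error and missing rate
  ihc_er <- ihc_pr <- ihc_her2 <- rep("missing", n)
  flip <- function(x, p = 0.03) ifelse(stats::runif(length(x)) < p,
                                       ifelse(x == "positive", "negative", "positive"), x)
  hr_pos <- subtype %in% c("ER+", "ER+/HER2+")
  her2_pos <- subtype %in% c("HER2+", "ER+/HER2+")
  ihc_er[is_tumor] <- flip(ifelse(hr_pos[is_tumor], "positive", "negative"))
  ihc_pr[is_tumor] <- flip(ifelse(hr_pos[is_tumor] & stats::runif(sum(is_tumor)) < 0.8,
                                  "positive", "negative"))
  ihc_her2[is_tumor] <- flip(ifelse(her2_pos[is_tumor], "positive", "negative"))
  miss <- is_tumor & stats::runif(n) < 0.05
  ihc_er[miss] <- ihc_pr[miss] <- ihc_her2[miss] <- "missing"

  ## PAM50 labels: compatible with the true subtype, LumB-skewed in cohort A
  pam50 <- rep("missing", n)
  draw_pam50 <- function(st, co) {
    probs <- switch(st,
      "ER+"       = if (identical(co, "A")) c(LumA = 0.35, LumB = 0.60, Normal = 0.05)
                    else                    c(LumA = 0.62, LumB = 0.33, Normal = 0.05),
      "ER+/HER2+" = c(LumB = 0.50, Her2 = 0.45, Normal = 0.05),
      "HER2+"     = c(Her2 = 0.92, Basal = 0.04, Normal = 0.04),
      "TN"        = c(Basal = 0.92, Her2 = 0.04, Normal = 0.04))
    sample(names(probs), 1L, prob = probs)
  }
  pam50[is_tumor] <- mapply(draw_pam50, tum_subtype, tum_cohort)

  clinical <- data.frame(
    sample_id = ids,
    cohort = c(tum_cohort, adj_cohort, rep("none", cfg$n_healthy + cfg$n_cell_line)),
    age = age, menopausal_status = meno, purity = purity,
    histology = histology, stage = stage,
    ihc_er = ihc_er, ihc_pr = ihc_pr, ihc_her2 = ihc_her2,
    pam50 = pam50, family_history = family_history,
    group_label = c(rep("tumor", length(tum_ids)),
                    rep("adjacent_normal", cfg$n_adjacent),
                    rep("healthy_normal", cfg$n_healthy),
                    rep("cell_line", cfg$n_cell_line)),
    stringsAsFactors = FALSE)

  ## ---- planted factor weights H (factors x samples)
  H <- matrix(0, k, n, dimnames = list(sim_factor_names, ids))
  for (i in seq_along(tum_ids)) {
    co <- tum_cohort[i]
    H[subtype_to_factor[tum_subtype[i]], i] <- rgamma_mean(1, 1, shape = 20)
    H["TIL", i]    <- rgamma_mean(1, cfg$til_mean[co])
    H["stroma", i] <- rgamma_mean(1, cfg$stroma_mean, shape = 3)
    H["adjacent", i] <- rgamma_mean(1, 0.08, shape = 4)
    H[paste0("batch_", co), i] <- rgamma_mean(1, 0.35)
  }
  adj_idx <- which(ids %in% adj_ids)
  for (i in adj_idx) {
    H["adjacent", i] <- rgamma_mean(1, 1, shape = 20)
    H["stroma", i]   <- rgamma_mean(1, 0.25)
    H["TIL", i]      <- rgamma_mean(1, cfg$adjacent_til)
    H["healthy", i]  <- rgamma_mean(1, 0.15, shape = 4)
  }
  hlt_idx <- which(ids %in% hlt_ids)
  for (i in hlt_idx) {
    H["healthy", i] <- rgamma_mean(1, 1, shape = 20)
    H["stroma", i]  <- rgamma_mean(1, 0.12, shape = 4)
    H["TIL", i]     <- rgamma_mean(1, 0.03, shape = 4)
  }
  cl_idx <- which(ids %in% cl_ids)
  for (i in cl_idx) H[subtype_to_factor[subtype[ids[i]]], i] <- rgamma_mean(1, 1.1, shape = 20)

  ## ---- planted gene weights W (genes x factors), exclusive marker blocks
  m <- cfg$markers_per_factor
  marker_names <- lapply(sim_factor_names, function(f) sprintf("%s_M%02d", f, seq_len(m)))
  names(marker_names) <- sim_factor_names
  ## canonical marker genes replace generated names (stay factor-exclusive)
  marker_names$TIL[1:2] <- c("GZMA", "PRF1")
  marker_names$stroma[1] <- "TGFB1"
  genes <- c(unlist(marker_names), "ESR1", "PGR", "ERBB2",
             sprintf("BG_%03d", seq_len(cfg$n_background_genes)))
  W <- matrix(0, length(genes), k, dimnames = list(genes, sim_factor_names))
  lo <- cfg$marker_weight_range[1]; hi <- cfg$marker_weight_range[2]
  for (f in sim_factor_names) W[marker_names[[f]], f] <- stats::runif(m, lo, hi)
  ## modest weights keep the TPM-scale CYT score near-linear in the TIL weight
  W["GZMA", "TIL"] <- 1.5; W["PRF1", "TIL"] <- 1.5
  ## receptor genes load on every factor whose subtype is receptor-positive
  W["ESR1", c("tumor_ER", "tumor_ERHER2")] <- 6
  W["PGR",  c("tumor_ER", "tumor_ERHER2")] <- 5.5
  W["ERBB2", c("tumor_HER2", "tumor_ERHER2")] <- 6.5
  bg <- grep("^BG_", genes, value = TRUE)
  W[bg, ] <- matrix(stats::runif(length(bg) * k, 0.2, 0.6), length(bg), k)

  ## ---- expression: V = W.H in log2(TPM+1) space, plus planted tumor DE shift
  V <- W %*% H
  de_tumor <- unlist(lapply(subtype_to_factor, function(f)
    marker_names[[f]][seq_len(min(cfg$de_tumor_genes_per_factor, m))]))
  A_tum <- seq_along(tum_ids)[tum_cohort == "A"]
  V[de_tumor, A_tum] <- V[de_tumor, A_tum] + cfg$de_tumor_log2fc
  tpm <- pmax(2^V - 1, 0)
  if (cfg$noise_sd > 0)
    tpm <- tpm * matrix(exp(stats::rnorm(length(tpm), 0, cfg$noise_sd)),
                        nrow(tpm), ncol(tpm))

  fractions_true <- sweep(H, 2, pmax(colSums(H), .Machine$double.eps), "/")

  structure(list(
    expression = tpm,
    clinical = clinical,
    truth = list(
      W_true = W, H_true = H, fractions_true = fractions_true,
      subtype = subtype,
      factor_labels = sim_factor_labels,
      markers = marker_names,
      de_genes = list(tme = marker_names$TIL, tumor = unname(de_tumor)),
      config = cfg)
  ), class = "bc_compendium")
}

#' @export
print.bc_compendium <- function(x, ...) {
  cl <- x$clinical
  cat("Synthetic breast-cancer compendium\n")
  cat(sprintf("  %d genes x %d samples\n", nrow(x$expression), ncol(x$expression)))
  print(table(cl$group_label, cl$cohort))
  invisible(x)
}

#' Simulate per-sample somatic mutation catalogs
#'
#' For every tumor sample, the mutation burden is Poisson with mean increasing
#' in patient age (log-linear slope), and 96-channel counts are multinomial
#' with channel probabilities `sum_i e_i s_i` where the exposures `e` come from
#' the sample's subtype template and `s_i` are catalog signature rows. Each
#' mutation is realised as a concrete ref/alt/flank record; about half are
#' emitted on the purine strand to exercise downstream pyrimidine
#' normalisation.
#'
#' @param cfg A [sim_config()].
#' @param clinical Cohort table from [simulate_compendium()].
#' @param truth Ground-truth list from [simulate_compendium()].
#' @param catalog Signature catalog matrix (signatures x 96), rows summing to 1;
#'   default [synthetic_signature_catalog()].
#' @return List: `mutations` (somatic mutation table) and `exposures_true`
#'   (sample x signature matrix of template exposures).
#' @export
simulate_mutation_catalogs <- function(cfg, clinical, truth,
                                       catalog = synthetic_signature_catalog()) {
  validate_sim_config(cfg)
  for (st in names(cfg$exposure_templates)) {
    tmpl <- cfg$exposure_templates[[st]]
    if (!all(names(tmpl) %in% rownames(catalog)))
      format_error("exposure template %s names signatures absent from the catalog", st)
  }
  set.seed(derive_seed(cfg$seed, 2L))
  ch <- channel_table()
  tum <- clinical$sample_id[clinical$group_label == "tumor"]
  expo <- matrix(0, length(tum), nrow(catalog), dimnames = list(tum, rownames(catalog)))
  out <- vector("list", length(tum))
  for (i in seq_along(tum)) {
    sid <- tum[i]
    st <- truth$subtype[sid]
    tmpl <- cfg$exposure_templates[[st]]
    expo[sid, names(tmpl)] <- tmpl
    age <- clinical$age[clinical$sample_id == sid]
    mu <- cfg$burden_base * exp(cfg$burden_age_slope * (age - 50))
    n_mut <- stats::rpois(1, mu)
    if (n_mut == 0) next
    p <- as.vector(expo[sid, ] %*% catalog)
    counts <- as.vector(stats::rmultinom(1, n_mut, p))
    out[[i]] <- realize_mutations(sid, counts, ch)
  }
  muts <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(muts))
    muts <- data.frame(sample_id = character(), gene = character(), chrom = character(),
                       pos = integer(), ref = character(), alt = character(),
                       context = character(), protein_altering = logical())
  rownames(muts) <- NULL
  list(mutations = muts, exposures_true = expo)
}

revcomp <- function(x) chartr("ACGT", "TGCA", vapply(x, function(s)
  paste(rev(strsplit(s, "")[[1L]]), collapse = ""), ""))

## Expand channel counts into concrete mutation records (random strand).
realize_mutations <- function(sid, counts, ch) {
  idx <- rep.int(seq_len(96L), counts)
  n <- length(idx)
  ref <- ch$ref[idx]; alt <- ch$alt[idx]
  ctx <- paste0(ch$five[idx], ref, ch$three[idx])
  flip <- stats::runif(n) < 0.5
  if (any(flip)) {
    ctx[flip] <- unname(revcomp(ctx[flip]))
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  }
  data.frame(sample_id = sid,
             gene = sprintf("G%05d", sample.int(20000L, n, replace = TRUE)),
             chrom = as.character(sample.int(22L, n, replace = TRUE)),
             pos = seq_len(n) * 150L,
             ref = ref, alt = alt, context = ctx,
             protein_altering = stats::runif(n) < 0.35,
             stringsAsFactors = FALSE)
}

#' Simulate germline carriers, copy number and TP53 mutations
#'
#' BRCA-like pathogenic carrier flags are enriched in younger patients and in
#' cohort A; ERBB2 amplification (CN >= 6) is assigned to HER2-positive
#' subtypes with a configurable leakage rate into other subtypes; TP53
#' protein-altering somatic mutations are enriched by subtype (highest in TN).
#'
#' @inheritParams simulate_mutation_catalogs
#' @return List: `germline` (germline call table), `cnv` (gene x sample copy
#'   numbers), `tp53` (somatic mutation amendments), `carrier` (named logical).
#' @export
simulate_genotypes <- function(cfg, clinical, truth) {
  validate_sim_config(cfg)
  set.seed(derive_seed(cfg$seed, 3L))
  tum <- clinical[clinical$group_label == "tumor", ]
  p_carrier <- stats::plogis(stats::qlogis(cfg$germline_rate[tum$cohort]) +
                             cfg$germline_age_coef * (40 - tum$age))
  carrier <- stats::runif(nrow(tum)) < p_carrier
  names(carrier) <- tum$sample_id
  germ <- if (any(carrier)) {
    ids <- tum$sample_id[carrier]
    trunc <- stats::runif(length(ids)) < 0.7
    data.frame(sample_id = ids,
               gene = sample(c("BRCA1", "BRCA2"), length(ids), replace = TRUE),
               consequence = ifelse(trunc, "truncating", "missense"),
               clinvar_pathogenic = !trunc | stats::runif(length(ids)) < 0.4,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(), gene = character(),
               consequence = character(), clinvar_pathogenic = logical())
  }

  ## copy number: ERBB2 amplified in HER2-positive subtypes (+ leakage)
  samp_st <- truth$subtype[clinical$sample_id]
  cn_genes <- c("ERBB2", "TP53", "PTEN", "MYC", "CCND1")
  cnv <- matrix(2, length(cn_genes), nrow(clinical),
                dimnames = list(cn_genes, clinical$sample_id))
  her2 <- !is.na(samp_st) & samp_st %in% c("HER2+", "ER+/HER2+")
  leak <- !is.na(samp_st) & !her2 & stats::runif(nrow(clinical)) < cfg$erbb2_leakage
  amp <- her2 | leak
  cnv["ERBB2", amp] <- sample(6:12, sum(amp), replace = TRUE)
  cnv[, clinical$group_label %in% c("adjacent_normal", "healthy_normal")] <- 2

  tp53_prev <- c("TN" = 0.875, "HER2+" = 0.75, "ER+/HER2+" = 0.643, "ER+" = 0.235)
  mut_p53 <- tum$sample_id[stats::runif(nrow(tum)) < tp53_prev[truth$subtype[tum$sample_id]]]
  tp53 <- data.frame(sample_id = mut_p53, gene = "TP53", chrom = "17",
                     pos = 7578000L + seq_along(mut_p53),
                     ref = "C", alt = "T", context = "ACG",
                     protein_altering = TRUE, stringsAsFactors = FALSE)
  list(germline = germ, cnv = cnv, tp53 = tp53, carrier = carrier)
}
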