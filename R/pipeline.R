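## Configuration and end-to-end pipeline orchestration.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration
#'
#' Every stage threshold of the analysis is a named, defaulted parameter here:
#' posterior call threshold and EM controls for subtyping, the CN >= 6
#' amplification threshold, exposure pruning (0.06), the 20% signature
#' prevalence filter, the S3 > 0.2 HRD rule, the NMF rank and 30 restarts,
#' the cohort-attribution ratio (2) and CYT correlation floor (0.5), the DE
#' thresholds (FDR < 0.01; fold-change > 2 or < 0.5; pathway |effect| > 0.2),
#' the 10-permutation association test (gene FDR <= 0.05, pathway r >= 0.6,
#' 0.2 categorisation margins) and the 500-bootstrap elastic net.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, subtype = TRUE, mutsig = TRUE, nmf = TRUE,
                  de = TRUE, associate = TRUE, multivariate = TRUE),
    sim = list(),
    subtype = list(posterior_threshold = 0.5, cnv_amp_threshold = 6,
                   em_tol = 1e-6, em_max_iter = 1000L),
    mutsig = list(prune = 0.06, min_prevalence = 0.2,
                  hrd_signature = "S3", hrd_threshold = 0.2),
    nmf = list(k = 10L, n_restarts = 30L, max_iter = 500L, tol = 1e-5,
               ratio = 2, r_min = 0.5, cyt_offset = 0.01),
    de = list(fdr = 0.01, fc = 2, effect_min = 0.2,
              mean_frac = 0.25, sd_frac = 0.25),
    associate = list(n_perm = 10L, mode = "signed", fdr_max = 0.05,
                     r_min = 0.6, margin = 0.2),
    multivariate = list(n_boot = 500L, alpha = 0.5, nfolds = 5L)
  )
}

#' Validate a pipeline configuration against the defaults
#'
#' Unknown keys (at the top level or within a stage section) raise a
#' validation error naming the key; known keys override the defaults.
#'
#' @param config Possibly partial configuration list.
#' @return The merged, validated configuration.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    format_error("config: unknown key(s): %s", paste(unknown, collapse = ", "))
  merged <- ref
  for (top in names(config)) {
    if (is.list(ref[[top]]) && top != "sim") {
      bad <- setdiff(names(config[[top]]), names(ref[[top]]))
      if (length(bad))
        format_error("config: unknown key(s) in section '%s': %s",
                     top, paste(bad, collapse = ", "))
      merged[[top]][names(config[[top]])] <- config[[top]]
    } else {
      merged[[top]] <- config[[top]]
    }
  }
  ## sim overrides are validated by sim_config itself
  do.call(sim_config, c(list(seed = merged$seed), merged$sim))
  merged
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with per-stage sections.
#' @return Validated configuration (defaults filled in).
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

write_stage <- function(df, outdir, name) {
  write_table_tsv(df, file.path(outdir, name))
}

#' Run the full analysis pipeline on a simulated compendium
#'
#' Chains all stages on the seeded synthetic compendium: simulation, subtype
#' consensus calling, mutational-signature refitting with prevalence filtering
#' and HRD calls, NMF virtual microdissection with compartment attribution,
#' covariate-adjusted differential expression of genes and pathway scores,
#' max-correlation attribution of DE features to compartments, and the
#' multivariate (elastic-net usage plus feature-by-covariate) analysis. All
#' stage outputs are written as TSV to `outdir` together with a
#' `manifest.json` recording the configuration, its hash and the seeds, so
#' that two runs with the same config and seed are byte-identical.
#'
#' @param config Configuration list (see [default_config()]); partial lists
#'   are merged with the defaults and validated.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("bcdissect_run_")) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- cfg$stages
  res <- list(config = cfg)

  if (!st$simulate) format_error("orchestration error: stage 'simulate' is required by all others")
  comp <- simulate_compendium(do.call(sim_config, c(list(seed = cfg$seed), cfg$sim)))
  catalog <- synthetic_signature_catalog()
  mut <- simulate_mutation_catalogs(comp$truth$config, comp$clinical, comp$truth, catalog)
  geno <- simulate_genotypes(comp$truth$config, comp$clinical, comp$truth)
  muts_all <- rbind(mut$mutations, geno$tp53)
  res$compendium <- comp
  res$mutations <- muts_all
  res$genotypes <- geno
  write_expression(comp$expression, file.path(outdir, "expression.tsv"))
  write_stage(comp$clinical, outdir, "clinical.tsv")
  write_stage(muts_all, outdir, "mutations.tsv")
  write_expression(geno$cnv, file.path(outdir, "cnv.tsv"))
  write_stage(geno$germline, outdir, "germline.tsv")

  clin <- comp$clinical
  tumors <- clin$sample_id[clin$group_label == "tumor"]
  tum_clin <- clin[match(tumors, clin$sample_id), ]

  if (st$subtype) {
    ihc <- ihc_subtype(tum_clin$ihc_er, tum_clin$ihc_pr, tum_clin$ihc_her2)
    pos_rate <- function(x) {
      known <- x[x != "missing"]
      min(max(mean(known == "positive"), 0.05), 0.95)
    }
    fr <- c(ESR1 = pos_rate(tum_clin$ihc_er), PGR = pos_rate(tum_clin$ihc_pr),
            ERBB2 = pos_rate(tum_clin$ihc_her2))
    nmc <- call_nmc(comp$expression[, tumors], geno$cnv, fr,
                    posterior_threshold = cfg$subtype$posterior_threshold,
                    cnv_amp_threshold = cfg$subtype$cnv_amp_threshold)
    cons <- consensus_subtype(ihc, nmc$subtype, tum_clin$pam50)
    cons <- cbind(sample_id = tumors, cons)
    res$subtype <- cons
    write_stage(cons, outdir, "subtype.tsv")
  }

  if (st$mutsig) {
    prof <- build_profile(muts_all, mode = "sample")
    nonzero <- colnames(prof)[colSums(prof) > 0]
    expos <- refit_exposures(unclass(prof)[, nonzero, drop = FALSE], catalog,
                             prune = cfg$mutsig$prune)
    emat <- exposure_matrix(expos)
    filt <- prevalence_filter(emat, tum_clin$cohort[match(rownames(emat), tumors)],
                              min_prevalence = cfg$mutsig$min_prevalence)
    hrd <- call_hrd(emat, cfg$mutsig$hrd_signature, cfg$mutsig$hrd_threshold)
    names(hrd) <- rownames(emat)
    res$exposures <- emat
    res$exposures_filtered <- filt
    res$hrd <- hrd
    write_stage(data.frame(sample_id = rownames(emat), emat,
                           hrd = hrd, check.names = FALSE), outdir, "exposures.tsv")
    ## group-wise pooled exposures per cohort
    pooled <- build_profile(muts_all, mode = "pooled",
                            groups = stats::setNames(tum_clin$cohort, tumors))
    pexp <- refit_exposures(unclass(pooled), catalog, prune = cfg$mutsig$prune)
    res$pooled_exposures <- exposure_matrix(pexp)
    write_stage(data.frame(group = rownames(res$pooled_exposures),
                           res$pooled_exposures, check.names = FALSE),
                outdir, "exposures_pooled.tsv")
  }

  if (st$nmf) {
    V <- log_tpm(comp$expression)
    model <- nmf_fit(V, k = cfg$nmf$k, n_restarts = cfg$nmf$n_restarts,
                     seed = cfg$seed, max_iter = cfg$nmf$max_iter, tol = cfg$nmf$tol)
    cyt <- cyt_score(comp$expression, offset = cfg$nmf$cyt_offset)
    subtype_all <- comp$truth$subtype
    if (st$subtype) subtype_all[tumors] <- res$subtype$consensus
    attribution <- attribute_compartments(model, clin, subtype_all, cyt,
                                          ratio = cfg$nmf$ratio, r_min = cfg$nmf$r_min)
    cohort_factors <- attribution$factor[startsWith(attribution$label, "cohort_specific")]
    model <- normalize_fractions(model, cohort_factors)
    model$attribution <- attribution
    exemplars <- extract_exemplars(model)
    res$model <- model
    res$cyt <- cyt
    res$exemplars <- exemplars
    write_expression(model$W, file.path(outdir, "W.tsv"))
    write_expression(model$H, file.path(outdir, "H.tsv"))
    write_expression(model$fractions, file.path(outdir, "fractions.tsv"))
    write_stage(exemplars, outdir, "exemplars.tsv")
    write_stage(attribution, outdir, "attribution.tsv")
  }

  if (st$de) {
    if (!st$nmf) format_error("orchestration error: stage 'de' needs stage 'nmf' for pathway sets")
    Vt <- log_tpm(comp$expression[, tumors])
    Vf <- filter_genes(Vt, cfg$de$mean_frac, cfg$de$sd_frac)
    covars <- data.frame(subtype = comp$truth$subtype[tumors],
                         purity = tum_clin$purity)
    de_genes <- de_test(Vf, tum_clin$cohort, covars, feature_type = "gene",
                        fdr = cfg$de$fdr, fc = cfg$de$fc)
    genesets <- c(comp$truth$markers,
                  list(HALLMARK_TGF_BETA_SIGNALING = comp$truth$markers$stroma))
    names(genesets)[seq_along(comp$truth$markers)] <-
      paste0("SET_", names(comp$truth$markers))
    write_gmt(genesets, file.path(outdir, "genesets.gmt"))
    scores <- score_pathways(log_tpm(comp$expression), genesets)
    de_pw <- de_test(scores[, tumors], tum_clin$cohort, covars,
                     feature_type = "pathway",
                     fdr = cfg$de$fdr, effect_min = cfg$de$effect_min)
    res$de_genes <- de_genes
    res$pathway_scores <- scores
    res$de_pathways <- de_pw
    write_stage(de_genes, outdir, "de_genes.tsv")
    write_stage(de_pw, outdir, "de_pathways.tsv")
  }

  if (st$associate) {
    if (!st$nmf || !st$de)
      format_error("orchestration error: stage 'associate' needs stages 'nmf' and 'de'")
    model <- res$model
    labels <- stats::setNames(model$attribution$label, model$attribution$factor)
    V <- log_tpm(comp$expression)
    de_hits <- res$de_genes$feature[res$de_genes$pass]
    assoc_g <- associate_features(V[de_hits, , drop = FALSE], model$fractions_all,
                                  n_perm = cfg$associate$n_perm, seed = cfg$seed,
                                  mode = cfg$associate$mode, feature_type = "gene",
                                  fdr_max = cfg$associate$fdr_max)
    assoc_g <- categorize(assoc_g, labels, margin = cfg$associate$margin)
    pw_hits <- res$de_pathways$feature[res$de_pathways$pass]
    assoc_p <- categorize(
      associate_features(res$pathway_scores[pw_hits, , drop = FALSE],
                         model$fractions_all, n_perm = cfg$associate$n_perm,
                         seed = cfg$seed, mode = cfg$associate$mode,
                         feature_type = "pathway", r_min = cfg$associate$r_min),
      labels, margin = cfg$associate$margin)
    res$associations_genes <- assoc_g
    res$associations_pathways <- assoc_p
    write_stage(assoc_g, outdir, "associations_genes.tsv")
    write_stage(assoc_p, outdir, "associations_pathways.tsv")
  }

  if (st$multivariate) {
    if (!st$nmf || !st$mutsig)
      format_error("orchestration error: stage 'multivariate' needs stages 'nmf' and 'mutsig'")
    til_factor <- res$model$attribution$factor[res$model$attribution$label == "TIL"][1]
    er_factor <- res$model$attribution$factor[
      res$model$attribution$label == "tumor_intrinsic:ER+"][1]
    frac_or_na <- function(f) if (is.na(f) || !f %in% rownames(res$model$fractions))
      rep(NA_real_, length(tumors)) else res$model$fractions[f, tumors]
    tgfb <- if (st$de) res$pathway_scores["HALLMARK_TGF_BETA_SIGNALING", tumors]
            else rep(NA_real_, length(tumors))
    tp53_mut <- as.integer(tumors %in% res$mutations$sample_id[
      res$mutations$gene == "TP53" & res$mutations$protein_altering])
    feats <- data.frame(
      S3 = res$exposures[match(tumors, rownames(res$exposures)), "S3"],
      TIL_factor = frac_or_na(til_factor),
      ER_factor = frac_or_na(er_factor),
      ESR1_exp = log_tpm(comp$expression)["ESR1", tumors],
      ERBB2_amp = as.integer(geno$cnv["ERBB2", tumors] >= cfg$subtype$cnv_amp_threshold),
      BRCA_mut = as.integer(geno$carrier[tumors]),
      TP53_mut = tp53_mut,
      TGFB_sig = tgfb)
    feats$S3[is.na(feats$S3)] <- 0
    usable <- colSums(is.na(feats)) == 0
    if (any(!usable))
      warning(sprintf("multivariate: dropping feature(s) with undefined values: %s",
                      paste(colnames(feats)[!usable], collapse = ", ")), call. = FALSE)
    feats <- feats[, usable, drop = FALSE]
    covars <- data.frame(
      cohort = tum_clin$cohort,
      age = tum_clin$age,
      purity = tum_clin$purity,
      er_status = comp$truth$subtype[tumors] %in% c("ER+", "ER+/HER2+"),
      menopausal = tum_clin$menopausal_status == "pre",
      lobular = tum_clin$histology == "lobular",
      late_stage = tum_clin$stage %in% c("III", "IV"))
    usage <- variable_usage(as.matrix(feats), tum_clin$cohort,
                            n_boot = cfg$multivariate$n_boot,
                            alpha = cfg$multivariate$alpha,
                            nfolds = cfg$multivariate$nfolds, seed = cfg$seed)
    mvr <- feature_covariate_matrix(feats, covars)
    res$usage <- usage
    res$multivariate <- mvr
    write_stage(data.frame(feature = names(usage), usage_pct = usage),
                outdir, "usage.tsv")
    write_stage(data.frame(feature = rownames(mvr$neglog10_p),
                           round(mvr$neglog10_p, 4), check.names = FALSE),
                outdir, "covariate_matrix.tsv")
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "bcdissect",
    version = as.character(utils::packageVersion("bcdissect")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tmp)),
    config = cfg,
    outputs = sort(list.files(outdir)))
  unlink(tmp)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(outdir, "manifest.json"))
  res$outdir <- outdir
  invisible(res)
}
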