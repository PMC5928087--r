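## ---- internal helpers -------------------------------------------------------

format_error <- function(...) stop(sprintf(...), call. = FALSE)

#' Canonical clinical factor levels
#'
#' Levels recognised by [read_clinical()]. Values outside these vocabularies are
#' mapped to `"missing"` with a warning rather than rejected, so that each
#' downstream stage can apply its own exclusion rule.
#' @keywords internal
clinical_levels <- list(
  menopausal_status = c("pre", "post", "peri", "missing"),
  histology         = c("ductal", "lobular", "other", "missing"),
  stage             = c("I", "II", "III", "IV", "missing"),
  ihc_er            = c("positive", "negative", "missing"),
  ihc_pr            = c("positive", "negative", "missing"),
  ihc_her2          = c("positive", "negative", "missing"),
  pam50             = c("LumA", "LumB", "Her2", "Basal", "Normal", "missing"),
  family_history    = c("yes", "no", "missing"),
  group_label       = c("tumor", "adjacent_normal", "healthy_normal", "cell_line")
)

#' Clinical subtype vocabulary
#' @keywords internal
subtype_levels <- c("ER+", "ER+/HER2+", "HER2+", "TN")

normalize_level <- function(x, levels, column) {
  x <- as.character(x)
  x[is.na(x) | x == "" | tolower(x) == "na"] <- "missing"
  idx <- match(tolower(x), tolower(levels))
  bad <- is.na(idx)
  if (any(bad)) {
    warning(sprintf("column '%s': %d value(s) outside {%s} mapped to 'missing' (e.g. '%s')",
                    column, sum(bad), paste(levels, collapse = ", "), x[bad][1]),
            call. = FALSE)
    idx[bad] <- match("missing", tolower(levels))
  }
  levels[idx]
}

## ---- expression / copy number matrices --------------------------------------

read_numeric_matrix <- function(path, what, nonneg = TRUE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error("%s file '%s': need a gene_id column plus >= 1 sample", what, path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) format_error("%s file '%s': duplicated gene id '%s'",
                                       what, path, ids[duplicated(ids)][1])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) format_error("%s file '%s': duplicated sample id '%s'",
                                           what, path, samples[duplicated(samples)][1])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) format_error("%s file '%s': missing or non-numeric entries", what, path)
  if (nonneg && any(m < 0)) format_error("%s file '%s': negative value %g (values must be >= 0)",
                                         what, path, min(m))
  dimnames(m) <- list(ids, samples)
  m
}

#' Read a gene-by-sample expression matrix (TPM)
#'
#' First column is the gene identifier, remaining columns one numeric column
#' per sample. Values are TPM and must be non-negative and complete; duplicated
#' gene or sample identifiers are rejected.
#'
#' @param path Path to a tab-separated file with header `gene_id<TAB>samples...`.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @seealso [write_expression()], [log_tpm()]
#' @export
read_expression <- function(path) read_numeric_matrix(path, "expression")

#' Write an expression (or copy-number) matrix as TSV
#'
#' Inverse of [read_expression()]; a write/read round trip reproduces values
#' bit-exactly (values are serialised at full double precision).
#'
#' @param mat Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level absolute copy-number table
#'
#' Same dialect as [read_expression()]; values are absolute copy numbers
#' (non-negative). The amplification predicate used throughout the package is
#' `CN >= 6`.
#' @inheritParams read_expression
#' @return Numeric matrix genes x samples.
#' @export
read_cnv <- function(path) read_numeric_matrix(path, "copy-number")

#' log2(TPM + 1) transform
#' @param tpm Non-negative expression matrix.
#' @export
log_tpm <- function(tpm) {
  if (any(tpm < 0)) format_error("log_tpm: negative TPM values")
  log2(tpm + 1)
}

## ---- clinical table ---------------------------------------------------------

#' Read a clinical covariate table
#'
#' Mandatory columns: `sample_id`, `cohort`, `group_label`. Optional columns
#' (`age`, `menopausal_status`, `purity`, `histology`, `stage`, `ihc_er`,
#' `ihc_pr`, `ihc_her2`, `pam50`, `family_history`) are typed and validated if
#' present; categorical values are matched case-insensitively against the
#' canonical vocabularies and unknown levels become `"missing"` with a warning.
#' Missingness is always encoded as an explicit `"missing"` level (or `NA` for
#' numeric columns), never dropped at load.
#'
#' @param path Path to a TSV whose header names columns exactly as above.
#' @return A `data.frame` with one row per sample, `sample_id` unique.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in c("sample_id", "cohort", "group_label")) {
    if (!col %in% colnames(df)) format_error("clinical file '%s': missing mandatory column '%s'", path, col)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    format_error("clinical file '%s': duplicated sample_id '%s'", path,
                 df$sample_id[duplicated(df$sample_id)][1])
  df$cohort <- as.character(df$cohort)
  for (col in intersect(names(clinical_levels), colnames(df))) {
    df[[col]] <- normalize_level(df[[col]], clinical_levels[[col]], col)
  }
  if ("age" %in% colnames(df)) {
    df$age <- suppressWarnings(as.numeric(df$age))
    if (any(!is.na(df$age) & df$age <= 0)) format_error("clinical file '%s': age must be > 0", path)
  }
  if ("purity" %in% colnames(df)) {
    df$purity <- suppressWarnings(as.numeric(df$purity))
    bad <- !is.na(df$purity) & (df$purity < 0 | df$purity > 1)
    if (any(bad)) format_error("clinical file '%s': purity outside [0,1] (%g)", path, df$purity[bad][1])
  }
  df
}

#' Write a clinical (or any typed) table as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- somatic mutations ------------------------------------------------------

BASES <- c("A", "C", "G", "T")

validate_mutations <- function(df, where) {
  need <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "context", "protein_altering")
  for (col in need) if (!col %in% colnames(df))
    format_error("mutation table %s: missing mandatory column '%s'", where, col)
  df$sample_id <- as.character(df$sample_id)
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$context <- toupper(as.character(df$context))
  df$protein_altering <- as.logical(df$protein_altering)
  if (any(df$ref == df$alt)) format_error("mutation table %s: ref == alt", where)
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  ctx_bad <- snv & nchar(df$context) == 3L & substr(df$context, 2L, 2L) != df$ref
  if (any(ctx_bad))
    format_error("mutation table %s: context middle base != ref in %d record(s) (e.g. %s ref %s)",
                 where, sum(ctx_bad), df$context[ctx_bad][1], df$ref[ctx_bad][1])
  df
}

#' Read a somatic mutation table (MAF-like TSV)
#'
#' Columns: `sample_id, gene, chrom, pos, ref, alt, context, protein_altering`.
#' Positions are 1-based; the trinucleotide `context` is the reference-strand
#' 3-mer centred on the mutated base (pyrimidine normalisation is deferred to
#' [build_profile()], keeping ingestion lossless). For SNVs the middle base of
#' the context must equal `ref`.
#'
#' @param path Path to TSV.
#' @return Typed `data.frame` of somatic mutations.
#' @export
read_mutations <- function(path) {
  ## colClasses: a bare "T" ref/alt must stay a base, not become logical TRUE
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  validate_mutations(df, sprintf("'%s'", path))
}

#' Read SNVs from a VCF plus caller-supplied trinucleotide contexts
#'
#' VCF records carry no flanking sequence, so the reference-strand context must
#' be supplied: either a character vector aligned with the VCF body rows, or a
#' function `(chrom, pos)` returning the 3-mer. Multi-allelic and non-SNV
#' records are dropped with a message. Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param contexts Character vector (one per VCF row) or function of
#'   `(chrom, pos)` returning reference 3-mers.
#' @param sample_id Sample identifier to assign to every record.
#' @param protein_altering Logical scalar or vector; default `NA` is stored.
#' @return Typed mutation `data.frame`, as [read_mutations()].
#' @export
read_mutations_vcf <- function(path, contexts, sample_id, protein_altering = NA) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    format_error("read_mutations_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.function(contexts)) {
    ctx <- mapply(contexts, fix$CHROM, as.integer(fix$POS), USE.NAMES = FALSE)
  } else {
    if (length(contexts) != nrow(fix))
      format_error("contexts: need %d values, got %d", nrow(fix), length(contexts))
    ctx <- as.character(contexts)
  }
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!keep)) message(sum(!keep), " non-SNV/multi-allelic VCF record(s) dropped")
  df <- data.frame(sample_id = sample_id,
                   gene = if ("ID" %in% colnames(fix)) fix$ID else NA_character_,
                   chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT, context = ctx,
                   protein_altering = protein_altering,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  validate_mutations(df, sprintf("'%s' (VCF)", path))
}

#' Read a germline call table
#'
#' Columns: `sample_id, gene, consequence, clinvar_pathogenic`. The pathogenic
#' predicate used downstream is `consequence == "truncating" OR
#' clinvar_pathogenic`.
#' @param path Path to TSV.
#' @export
read_germline <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("sample_id", "gene", "consequence", "clinvar_pathogenic"))
    if (!col %in% colnames(df)) format_error("germline file '%s': missing mandatory column '%s'", path, col)
  df$consequence <- normalize_level(df$consequence,
                                    c("truncating", "missense", "other", "missing"),
                                    "consequence")
  df$clinvar_pathogenic <- as.logical(df$clinvar_pathogenic)
  df
}

#' Pathogenic predicate for germline calls
#' @param germline A germline call table.
#' @return Logical vector: truncating consequence or ClinVar-pathogenic.
#' @export
is_pathogenic <- function(germline) {
  germline$consequence == "truncating" | (germline$clinvar_pathogenic %in% TRUE)
}

## ---- gene sets --------------------------------------------------------------

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member genes...`.
#' @param path Path to GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) format_error("GMT '%s': line with < 3 fields: '%s'", path, l)
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  if (anyDuplicated(names(sets))) format_error("GMT '%s': duplicated set name", path)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(n, d, g) paste(c(n, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
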