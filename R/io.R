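# Readers and writers for every tabular format the pipeline touches, with
# strict row-level validation. All coordinates are 1-based GRCh37-style; no
# liftover is attempted. Column names are fixed snake_case; a `col_map`
# rename vector adapts foreign headers so the parsers stay dialect-free.

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
EQTL_EXTRA_COLS <- c("gene", "fdr")

MR_RESULT_COLS <- c("gene", "method", "nsnp", "beta", "se", "pval", "qval",
                    "or_point", "ci_low", "ci_high",
                    "steiger_correct", "steiger_pval")
MR_SENSITIVITY_COLS <- c("q_stat", "q_pval",
                         "egger_beta", "egger_se", "egger_pval",
                         "egger_intercept", "egger_intercept_se",
                         "egger_intercept_pval",
                         "wm_beta", "wm_se", "wm_pval")
COLOC_RESULT_COLS <- c("gene", "n_snps", "pp0", "pp1", "pp2", "pp3", "pp4",
                       "colocalized")
DRUG_TABLE_COLS <- c("gene", "drug_name", "action_type", "max_phase",
                     "broad_spectrum", "safety_established", "approved")
GENE_ANNOTATION_COLS <- c("symbol", "chrom", "tss", "druggable_tier")

read_tsv_raw <- function(path) {
  if (!file.exists(path)) {
    dgmr_abort(sprintf("file not found: %s", path), "dgmr_io_error")
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  if (is.null(names(col_map))) {
    dgmr_abort("`col_map` must be a named character vector (canonical = foreign)",
               "dgmr_usage_error")
  }
  for (canonical in names(col_map)) {
    foreign <- col_map[[canonical]]
    hit <- which(names(df) == foreign)
    if (length(hit)) names(df)[hit[1L]] <- canonical
  }
  df
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    dgmr_abort(sprintf("%s: missing required column(s): %s", path,
                       paste(missing, collapse = ", ")),
               "dgmr_schema_error")
  }
  invisible(df)
}

fail_rows <- function(bad, reason, path) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    shown <- utils::head(rows, 5L)
    dgmr_abort(sprintf("%s: %s on row(s) %s%s", path, reason,
                       paste(shown, collapse = ", "),
                       if (length(rows) > 5L) sprintf(" (and %d more)",
                                                      length(rows) - 5L) else ""),
               "dgmr_validation_error")
  }
}

#' Validate a summary-statistics data frame in place
#'
#' Enforces the record invariants: single-base A/C/G/T alleles (uppercased;
#' indels rejected), effect allele distinct from other allele, `se > 0`,
#' `pval` in (0, 1], `eaf` in \[0, 1\] (missing permitted only for GWAS
#' records, where it is needed solely for palindromic SNPs), `pos >= 1`,
#' `n >= 1`; eQTL records additionally need `gene` and `fdr` in \[0, 1\].
#' Offending 1-based data-row numbers are reported.
#'
#' @param df data frame of summary statistics.
#' @param kind `"gwas"` or `"eqtl"`.
#' @param path label used in error messages.
#' @return the validated data frame, alleles uppercased.
#' @export
validate_summary_stats <- function(df, kind = c("gwas", "eqtl"),
                                   path = "<summary stats>") {
  kind <- match.arg(kind)
  need <- if (kind == "eqtl") c(SUMSTAT_COLS, EQTL_EXTRA_COLS) else SUMSTAT_COLS
  require_columns(df, need, path)
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  fail_rows(!(df$effect_allele %in% ALLELES),
            "effect_allele is not a single A/C/G/T base", path)
  fail_rows(!(df$other_allele %in% ALLELES),
            "other_allele is not a single A/C/G/T base", path)
  fail_rows(df$effect_allele == df$other_allele,
            "effect_allele equals other_allele", path)
  fail_rows(!is.finite(df$se) | df$se <= 0, "se must be > 0", path)
  fail_rows(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
            "pval must lie in (0, 1]", path)
  fail_rows(!is.finite(df$pos) | df$pos < 1 | df$pos != round(df$pos),
            "pos must be a 1-based integer position", path)
  fail_rows(!is.finite(df$n) | df$n < 1, "n must be >= 1", path)
  if (kind == "eqtl") {
    fail_rows(is.na(df$eaf), "eaf is required for eQTL records", path)
  }
  fail_rows(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
            "eaf must lie in [0, 1]", path)
  fail_rows(!is.finite(df$beta), "beta must be finite", path)
  if (kind == "eqtl") {
    df$gene <- as.character(df$gene)
    df$fdr <- suppressWarnings(as.numeric(df$fdr))
    fail_rows(is.na(df$gene) | df$gene == "", "gene symbol is required", path)
    fail_rows(!is.finite(df$fdr) | df$fdr < 0 | df$fdr > 1,
              "fdr must lie in [0, 1]", path)
  }
  df$pos <- as.integer(df$pos)
  df
}

#' Read a GWAS or eQTL summary-statistics table
#'
#' Expects a tab-separated file with a header naming the canonical columns
#' `snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n`
#' (plus `gene` and `fdr` for eQTL tables). `#`-prefixed lines are ignored.
#'
#' @param path file path.
#' @param kind `"gwas"` or `"eqtl"`; eQTL tables carry per-record gene and FDR.
#' @param col_map optional named character vector renaming foreign headers,
#'   e.g. `c(snp_id = "SNP", pval = "p")`.
#' @return a validated data frame, one SNP association per row, input order
#'   preserved.
#' @export
read_summary_stats <- function(path, kind = c("gwas", "eqtl"),
                               col_map = NULL) {
  kind <- match.arg(kind)
  df <- apply_col_map(read_tsv_raw(path), col_map)
  validate_summary_stats(df, kind, path)
}

#' Write a summary-statistics table
#'
#' @param df validated summary-statistics data frame.
#' @param path output path.
#' @export
write_summary_stats <- function(df, path) {
  cols <- intersect(c(SUMSTAT_COLS, EQTL_EXTRA_COLS), names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square LD correlation matrix
#'
#' Format: TSV whose first row and first column carry SNP identifiers. The
#' matrix must be square, have entries within \[-1, 1\] (tolerance 1e-8) and
#' be symmetric within 1e-8; it is then exactly symmetrized as (M + t(M))/2
#' and the diagonal is forced to 1.
#'
#' @param path file path.
#' @return numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2L) {
    dgmr_abort(sprintf("%s: LD matrix needs an id column plus values", path),
               "dgmr_format_error")
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    dgmr_abort(sprintf("%s: LD matrix is not square (%d x %d)",
                       path, nrow(m), ncol(m)), "dgmr_format_error")
  }
  if (!identical(colnames(m), ids)) {
    dgmr_abort(sprintf("%s: LD row ids do not match column ids", path),
               "dgmr_format_error")
  }
  if (anyNA(m)) {
    dgmr_abort(sprintf("%s: LD matrix contains missing values", path),
               "dgmr_validation_error")
  }
  if (any(abs(m) > 1 + 1e-8)) {
    dgmr_abort(sprintf("%s: LD correlations must lie in [-1, 1]", path),
               "dgmr_validation_error")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    dgmr_abort(sprintf("%s: LD matrix asymmetric beyond 1e-8", path),
               "dgmr_validation_error")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

#' Write an LD matrix in the package's TSV layout
#' @param m square correlation matrix with SNP-id dimnames.
#' @param path output path.
#' @export
write_ld_matrix <- function(m, path) {
  df <- data.frame(snp_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation panel
#'
#' TSV with columns `symbol, chrom, tss, druggable_tier`; the tier is 1-3
#' (Tier 1 = targets of approved/clinical drugs, Tier 2 = proteins similar
#' to drug targets or with drug-like ligands, Tier 3 = extracellular or key
#' family members) or NA for non-druggable genes. Symbols must be unique.
#'
#' @param path file path.
#' @return data frame of gene annotations.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, GENE_ANNOTATION_COLS, path)
  df$symbol <- as.character(df$symbol)
  df$chrom <- as.character(df$chrom)
  df$tss <- suppressWarnings(as.numeric(df$tss))
  df$druggable_tier <- suppressWarnings(as.integer(df$druggable_tier))
  fail_rows(!is.finite(df$tss) | df$tss < 1 | df$tss != round(df$tss),
            "tss must be a 1-based integer position", path)
  fail_rows(!is.na(df$druggable_tier) & !(df$druggable_tier %in% 1:3),
            "druggable_tier must be 1, 2, 3 or NA", path)
  if (anyDuplicated(df$symbol)) {
    dgmr_abort(sprintf("%s: duplicated gene symbol(s): %s", path,
                       paste(unique(df$symbol[duplicated(df$symbol)]),
                             collapse = ", ")),
               "dgmr_validation_error")
  }
  df$tss <- as.integer(df$tss)
  df
}

#' Write a gene annotation panel
#' @param df gene annotation data frame.
#' @param path output path.
#' @export
write_gene_annotation <- function(df, path) {
  utils::write.table(df[, GENE_ANNOTATION_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounder-SNP blocklist
#'
#' One SNP id per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of SNP ids.
#' @export
read_blocklist <- function(path) {
  if (!file.exists(path)) {
    dgmr_abort(sprintf("file not found: %s", path), "dgmr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a confounder-SNP blocklist
#' @param snp_ids character vector of SNP ids.
#' @param path output path.
#' @export
write_blocklist <- function(snp_ids, path) {
  writeLines(c("# confounder-associated SNPs excluded from instruments",
               snp_ids), path)
  invisible(path)
}

DRUG_PHASES <- c("1", "2", "3", "approved")

#' Read a gene-to-drug candidate table
#'
#' TSV with columns `gene, drug_name, action_type, max_phase,
#' broad_spectrum, safety_established, approved` (and optionally
#' `level_passed`). `max_phase` is one of 1/2/3/approved; the three boolean
#' columns encode the curated Level I-III judgments.
#'
#' @param path file path.
#' @return data frame of drug candidates.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_raw(path)
  require_columns(df, DRUG_TABLE_COLS, path)
  df$gene <- as.character(df$gene)
  df$drug_name <- as.character(df$drug_name)
  df$action_type <- as.character(df$action_type)
  df$max_phase <- as.character(df$max_phase)
  fail_rows(!(df$max_phase %in% DRUG_PHASES),
            "max_phase must be one of 1, 2, 3, approved", path)
  for (col in c("broad_spectrum", "safety_established", "approved")) {
    df[[col]] <- as.logical(df[[col]])
    fail_rows(is.na(df[[col]]), sprintf("%s must be TRUE/FALSE", col), path)
  }
  if (!"level_passed" %in% names(df)) df$level_passed <- NA_integer_
  df
}

result_schema <- function(df) {
  if (all(COLOC_RESULT_COLS %in% names(df))) return("coloc")
  if (all(MR_RESULT_COLS %in% names(df))) return("mr")
  if (all(DRUG_TABLE_COLS %in% names(df))) return("drug")
  NA_character_
}

#' Write a homogeneous result table (MR, colocalization or drug candidates)
#'
#' Columns are emitted in a fixed order with floating point values rounded
#' to 7 significant digits, so re-reading reproduces every value within
#' 1e-6 relative. A list of per-row data frames is accepted provided all rows
#' share one schema; mixing result types is a usage error.
#'
#' @param results data frame (or list of data frames sharing a schema) of
#'   MR results, colocalization results, or drug candidates.
#' @param path output path.
#' @param header optional character vector of comment lines (without `#`)
#'   written above the table.
#' @export
write_results <- function(results, path, header = NULL) {
  if (is.list(results) && !is.data.frame(results)) {
    schemas <- vapply(results, result_schema, character(1L))
    if (length(unique(schemas)) > 1L || anyNA(schemas)) {
      dgmr_abort("mixed or unrecognized result types in `results`",
                 "dgmr_usage_error")
    }
    results <- do.call(rbind, results)
  }
  schema <- result_schema(results)
  if (is.na(schema)) {
    dgmr_abort("`results` does not match an MR, colocalization or drug schema",
               "dgmr_usage_error")
  }
  cols <- switch(schema,
                 mr = c(MR_RESULT_COLS,
                        intersect(MR_SENSITIVITY_COLS, names(results))),
                 coloc = COLOC_RESULT_COLS,
                 drug = c(DRUG_TABLE_COLS, "level_passed"))
  if (schema == "drug" && !"level_passed" %in% names(results)) {
    results$level_passed <- NA_integer_
  }
  out <- results[, cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], signif, digits = 7L)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  suppressWarnings(
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  )
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path file path.
#' @param kind `"mr"`, `"coloc"` or `"drug"`.
#' @return data frame.
#' @export
read_results <- function(path, kind = c("mr", "coloc", "drug")) {
  kind <- match.arg(kind)
  df <- read_tsv_raw(path)
  need <- switch(kind, mr = MR_RESULT_COLS, coloc = COLOC_RESULT_COLS,
                 drug = DRUG_TABLE_COLS)
  require_columns(df, need, path)
  for (col in names(df)) {
    if (is.integer(df[[col]]) &&
        !col %in% c("nsnp", "n_snps", "level_passed")) {
      df[[col]] <- as.double(df[[col]])
    }
  }
  df
}
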