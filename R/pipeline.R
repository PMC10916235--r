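# End-to-end orchestration: instruments -> harmonize -> MR -> coloc ->
# prioritize, with a run manifest recording the config hash, seed and the
# per-stage attrition funnel. Re-running with the same config and inputs
# reproduces byte-identical outputs; the only stochastic internal (the
# weighted-median bootstrap) is seed-controlled.

#' Default pipeline configuration
#'
#' Every tunable of the analysis in one flat list, units in the key names:
#' `window_bp` 100000 (cis window, inclusive boundary), `fdr_threshold`
#' 0.05 (strict, both for instrument FDR and MR q-values), `clump_r2`
#' 0.001, coloc priors `p1`/`p2`/`p12` = 1e-4/1e-4/1e-5, `pp4_threshold`
#' 0.75 (strict), `palindrome_eaf_limit` 0.42, `freq_tolerance` 0.2,
#' `ivw_model` "fixed", `wald_second_order` FALSE, `wm_boot` 1000,
#' `f_min` NULL (report F statistics without filtering), `seed` 1.
#'
#' @param ... overrides.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(window_bp = 100000L, fdr_threshold = 0.05, clump_r2 = 0.001,
              p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, pp4_threshold = 0.75,
              palindrome_eaf_limit = 0.42, freq_tolerance = 0.2,
              ivw_model = "fixed", wald_second_order = FALSE,
              wm_boot = 1000L, f_min = NULL, seed = 1L,
              tissue = "blood")
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$window_bp < 0 || cfg$clump_r2 < 0 || cfg$clump_r2 > 1) {
    dgmr_abort("window_bp must be >= 0 and clump_r2 in [0, 1]",
               "dgmr_parameter_error")
  }
  stopifnot_scalar_prob(cfg$fdr_threshold, "fdr_threshold")
  stopifnot_scalar_prob(cfg$pp4_threshold, "pp4_threshold")
  stopifnot_scalar_prob(cfg$palindrome_eaf_limit, "palindrome_eaf_limit")
  invisible(cfg)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg),
                   vapply(cfg, function(x) paste(format(x), collapse = ","),
                          character(1L)),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

stage_header <- function(cfg, hash) {
  c(sprintf("dgmr %s", as.character(utils::packageVersion("dgmr"))),
    sprintf("seed=%d config_hash=%s", as.integer(cfg$seed), hash))
}

#' Run the full drug-target MR pipeline
#'
#' Stages, each written to `output_dir` before the next begins:
#' instrument selection (`instruments.tsv`), harmonization ledger
#' (`harmonization.tsv`), per-gene MR with family FDR (`mr_results.tsv`),
#' colocalization of MR-significant genes (`coloc_results.tsv`), target
#' prioritization joined with drug candidates (`prioritized.tsv`), the
#' publication-style summary table (`forest_table.tsv`) and a JSON manifest
#' with the config hash, seed and per-stage counts (`manifest.json`).
#'
#' @param bundle input bundle list (see [simulate_study()]) or a directory
#'   containing the TSV bundle layout of [write_bundle()].
#' @param config configuration list from [default_config()].
#' @param output_dir output directory (created if needed).
#' @return invisible list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(bundle, config = default_config(),
                         output_dir = tempfile("dgmr_run_")) {
  validate_config(config)
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  header <- stage_header(config, hash)
  tissue <- config$tissue %||% bundle$tissue %||% NA_character_

  instruments <- select_instruments(bundle$eqtl, bundle$genes, bundle$ld,
                                    bundle$blocklist,
                                    window_bp = config$window_bp,
                                    fdr_threshold = config$fdr_threshold,
                                    clump_r2 = config$clump_r2,
                                    f_min = config$f_min)
  funnel <- attr(instruments, "funnel")
  write_stage_tsv(instruments, file.path(output_dir, "instruments.tsv"),
                  header)

  mr <- mr_all_genes(instruments, bundle$gwas, config)
  ledger <- attr(mr, "ledger")
  write_stage_tsv(ledger, file.path(output_dir, "harmonization.tsv"), header)
  write_results(mr, file.path(output_dir, "mr_results.tsv"), header)

  significant <- mr$gene[mr$qval < config$fdr_threshold]
  coloc <- run_coloc(bundle$eqtl, bundle$gwas, significant,
                     p1 = config$p1, p2 = config$p2, p12 = config$p12,
                     pp4_threshold = config$pp4_threshold)
  write_results(coloc, file.path(output_dir, "coloc_results.tsv"), header)

  targets <- prioritize_targets(mr, coloc, fdr = config$fdr_threshold,
                                pp4 = config$pp4_threshold, tissue = tissue)
  prioritized <- repurposing_table(targets, bundle$drugs)
  write_stage_tsv(prioritized, file.path(output_dir, "prioritized.tsv"),
                  header)

  forest <- make_forest_table(mr, coloc, tissue = tissue)
  write_stage_tsv(forest, file.path(output_dir, "forest_table.tsv"), header)

  manifest <- list(
    package = "dgmr",
    version = as.character(utils::packageVersion("dgmr")),
    seed = as.integer(config$seed),
    config_hash = hash,
    config = config[order(names(config))],
    counts = list(
      genes_in = unname(funnel[["genes_in"]]),
      genes_druggable = unname(funnel[["genes_druggable"]]),
      candidates_cis = unname(funnel[["candidates_cis"]]),
      candidates_blocked = unname(funnel[["candidates_blocked"]]),
      instruments_selected = unname(funnel[["instruments"]]),
      genes_with_instruments = unname(funnel[["genes_with_instruments"]]),
      genes_tested = nrow(mr),
      genes_mr_significant = length(significant),
      genes_colocalized = sum(coloc$colocalized),
      targets_prioritized = length(unique(prioritized$gene))
    ))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(instruments = instruments, ledger = ledger, mr = mr,
                 coloc = coloc, targets = targets,
                 prioritized = prioritized, forest = forest,
                 manifest = manifest, output_dir = output_dir))
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  suppressWarnings(
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' Publication-style per-gene summary table
#'
#' Joins MR and colocalization results by gene into forest-plot-ready rows:
#' formatted `OR (95% CI)`, q-value, the five posteriors and a tissue color
#' key, ordered by tissue then ascending q-value.
#'
#' @param mr_results `MrResult` data frame.
#' @param coloc_results `ColocResult` data frame.
#' @param tissue tissue label (also the color key field).
#' @return data frame, header-only when `mr_results` is empty.
#' @export
make_forest_table <- function(mr_results, coloc_results,
                              tissue = NA_character_) {
  empty <- data.frame(gene = character(0), tissue = character(0),
                      method = character(0), nsnp = integer(0),
                      or_ci = character(0), qval = numeric(0),
                      pp0 = numeric(0), pp1 = numeric(0), pp2 = numeric(0),
                      pp3 = numeric(0), pp4 = numeric(0),
                      color_key = character(0), stringsAsFactors = FALSE)
  if (!nrow(mr_results)) return(empty)
  merged <- merge(mr_results, coloc_results[, c("gene", "pp0", "pp1", "pp2",
                                                "pp3", "pp4")],
                  by = "gene", all.x = TRUE)
  out <- data.frame(gene = merged$gene, tissue = tissue,
                    method = merged$method, nsnp = merged$nsnp,
                    or_ci = sprintf("%.2f (%.2f, %.2f)", merged$or_point,
                                    merged$ci_low, merged$ci_high),
                    qval = merged$qval, pp0 = merged$pp0, pp1 = merged$pp1,
                    pp2 = merged$pp2, pp3 = merged$pp3, pp4 = merged$pp4,
                    color_key = tissue, stringsAsFactors = FALSE)
  out <- out[order(out$tissue, out$qval), , drop = FALSE]
  rownames(out) <- NULL
  out
}
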