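# File-level orchestration behind the command-line script: read inputs,
# run the analysis, write results/nulls/log with a provenance echo of the
# resolved configuration.

#' Run a full analysis from files
#'
#' Reads a signal matrix, a target table (or derives PCA latent factors, or
#' consumes a precomputed FCS matrix), and a BED-directory region set
#' database; runs [cocoa()]; writes `results.tsv` (ranked region sets),
#' `nulls.tsv` (per-set gamma parameters and p-value source),
#' `resolved_config.tsv` and `run.log` into `out_dir`.
#'
#' @param signal_path signal matrix TSV (see [read_signal_matrix()]); may be
#'   `NULL` when `fcs_path` is given.
#' @param regiondb_dir directory of BED files (see [load_region_db()]).
#' @param out_dir output directory, created if needed.
#' @param targets_path optional target table TSV; when `NULL` and no FCS is
#'   given, `n_pcs` PCA factors are derived from the signal.
#' @param fcs_path optional precomputed FCS matrix TSV (skips Step 1).
#' @param resolution signal resolution.
#' @param annotation optional region database annotation sheet.
#' @inheritParams cocoa
#' @inheritParams read_signal_matrix
#' @return the fitted [cocoa()] object, invisibly.
#' @export
cocoa_pipeline <- function(signal_path, regiondb_dir, out_dir,
                           targets_path = NULL, fcs_path = NULL,
                           resolution = c("nucleotide", "region"),
                           metric = "auto", stat = "mean", use_abs = TRUE,
                           min_covered_regions = 100, n_perm = 300,
                           p_method = "auto", n_pcs = 5, one_based = TRUE,
                           annotation = NULL, normalize_chrom = FALSE,
                           seed = 1) {
  resolution <- match.arg(resolution)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)

  db <- load_region_db(regiondb_dir, annotation = annotation,
                       normalize_chrom = normalize_chrom)
  logf("loaded region database: ", length(db), " sets from ", regiondb_dir)

  signal <- NULL
  fcs <- NULL
  targets <- NULL
  if (!is.null(fcs_path)) {
    fcs <- read_fcs_matrix(fcs_path, resolution = resolution,
                           one_based = one_based,
                           normalize_chrom = normalize_chrom)
    logf("precomputed FCS: ", nrow(fcs$values), " loci x ",
         ncol(fcs$values), " targets (Step 1 skipped)")
  } else {
    signal <- read_signal_matrix(signal_path, resolution = resolution,
                                 one_based = one_based,
                                 normalize_chrom = normalize_chrom)
    logf("signal: ", nrow(signal$values), " loci x ", ncol(signal$values),
         " samples, ", resolution, " resolution")
    if (!is.null(targets_path)) {
      targets <- read_target_table(targets_path)
      logf("targets: ", ncol(targets$values), " variable(s)")
    } else {
      logf("no targets given: deriving ", n_pcs, " PCA latent factors")
    }
  }

  fit <- withCallingHandlers(
    cocoa(signal, targets = targets, region_db = db, fcs = fcs,
          metric = metric, stat = stat, use_abs = use_abs,
          min_covered_regions = min_covered_regions, n_perm = n_perm,
          p_method = p_method, n_pcs = n_pcs, seed = seed),
    message = function(m) {
      logf(trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )

  write_results(fit$results, file.path(out_dir, "results.tsv"))
  if (!is.null(fit$null)) {
    nt <- merge(fit$null$gamma,
                fit$results[c("region_set", "target", "p_source")],
                by = c("region_set", "target"), sort = TRUE)
    utils::write.table(nt, file.path(out_dir, "nulls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- data.frame(
    key = c("signal", "targets", "fcs", "regiondb", "resolution", "metric",
            "stat", "use_abs", "min_covered_regions", "n_perm", "p_method",
            "n_pcs", "seed"),
    value = c(signal_path %||% "", targets_path %||% "", fcs_path %||% "",
              regiondb_dir, resolution, fit$metric, stat, use_abs,
              min_covered_regions, n_perm, p_method, n_pcs, seed)
  )
  utils::write.table(cfg, file.path(out_dir, "resolved_config.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("wrote results for ", length(unique(fit$results$region_set)),
       " region set(s) to ", out_dir)
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
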