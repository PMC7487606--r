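#' Construct an epigenetic signal matrix
#'
#' Rows are genomic loci (single CpGs at nucleotide resolution, peak regions
#' at region resolution), columns are samples. Values are signal intensities:
#' DNA methylation beta values in `[0, 1]`, or count-like chromatin
#' accessibility.
#'
#' @param coords interval data.frame, one row per locus (0-based half-open).
#' @param values numeric matrix, loci x samples; column names are sample ids.
#' @param resolution `"nucleotide"` (every locus is a single base) or
#'   `"region"`.
#' @param methylation if `TRUE`, values are checked to lie in `[0, 1]`
#'   (missing values allowed).
#' @return object of class `signal_matrix`.
#' @export
signal_matrix <- function(coords, values,
                          resolution = c("nucleotide", "region"),
                          methylation = FALSE) {
  resolution <- match.arg(resolution)
  coords <- validate_regions(coords, "coords")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(coords) != nrow(values)) {
    stop("coords and values must have the same number of rows")
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    stop("values must have sample ids as column names")
  }
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  if (resolution == "nucleotide" && any(coords$end - coords$start != 1)) {
    stop("nucleotide resolution requires single-base loci (end - start = 1)")
  }
  if (methylation) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      stop("methylation values must lie in [0, 1]")
    }
  }
  structure(
    list(coords = coords, values = values, resolution = resolution,
         methylation = methylation),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$values), " loci x ", ncol(x$values),
      " samples, ", x$resolution, " resolution",
      if (x$methylation) ", methylation [0,1]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

sample_ids <- function(signal) colnames(signal$values)

#' Construct a target-variable table
#'
#' Target variables are the per-sample quantities whose covariation with the
#' epigenome is being annotated: a supervised phenotype (e.g. a clinical
#' score) or an unsupervised latent factor (e.g. a principal component
#' score). Targets constant across samples carry no variation to annotate
#' and are dropped with a warning.
#'
#' @param values numeric matrix or data.frame, samples x targets; row names
#'   are sample ids, column names are target names.
#' @return object of class `target_variables`.
#' @export
target_variables <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values must have sample ids as row names")
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("target names must be present and unique")
  }
  sds <- apply(values, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sds) & sds == 0
  if (any(constant)) {
    warning("dropping constant target variable(s): ",
            paste(colnames(values)[constant], collapse = ", "))
    values <- values[, !constant, drop = FALSE]
  }
  if (ncol(values) == 0L) stop("no non-constant target variables left")
  structure(list(values = values), class = "target_variables")
}

#' @export
print.target_variables <- function(x, ...) {
  cat("<target_variables> ", nrow(x$values), " samples x ",
      ncol(x$values), " targets: ",
      paste(utils::head(colnames(x$values), 5L), collapse = ", "),
      if (ncol(x$values) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Align a target table to a signal matrix's samples (set equality required).
align_targets <- function(signal, targets) {
  if (!inherits(targets, "target_variables")) targets <- target_variables(targets)
  sid <- sample_ids(signal)
  tid <- rownames(targets$values)
  if (!setequal(sid, tid)) {
    missing <- setdiff(sid, tid)
    extra <- setdiff(tid, sid)
    stop("sample ids of signal and targets differ",
         if (length(missing)) paste0("; missing from targets: ",
                                     paste(utils::head(missing, 5L), collapse = ", ")),
         if (length(extra)) paste0("; absent from signal: ",
                                   paste(utils::head(extra, 5L), collapse = ", ")))
  }
  targets$values <- targets$values[sid, , drop = FALSE]
  targets
}
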