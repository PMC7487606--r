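# Step 1: feature contribution scores -- per-locus association between the
# epigenetic signal and each target variable.

#' Feature contribution score container
#'
#' @param values numeric matrix, loci x targets.
#' @param coords interval data.frame aligned to the rows (optional but
#'   required for scoring).
#' @param resolution signal resolution the scores derive from.
#' @param metric association metric that produced the scores.
#' @param abs_applied whether absolute values have already been taken.
#' @return object of class `feature_contribution_scores`.
#' @export
feature_contribution_scores <- function(values, coords = NULL,
                                        resolution = c("nucleotide", "region"),
                                        metric = "precomputed",
                                        abs_applied = FALSE) {
  resolution <- match.arg(resolution)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("FCS columns must carry target names")
  if (!is.null(coords)) {
    coords <- validate_regions(coords, "coords")
    if (nrow(coords) != nrow(values)) {
      stop("coords and FCS values must have the same number of rows")
    }
  }
  structure(
    list(values = values, coords = coords, resolution = resolution,
         metric = metric, abs_applied = abs_applied),
    class = "feature_contribution_scores"
  )
}

#' @export
print.feature_contribution_scores <- function(x, ...) {
  cat("<feature_contribution_scores> ", nrow(x$values), " loci x ",
      ncol(x$values), " targets (", x$metric,
      if (x$abs_applied) ", |abs|" else "", ")\n", sep = "")
  invisible(x)
}

#' Compute feature contribution scores
#'
#' Quantifies, for every genomic locus, how strongly its signal covaries
#' with each target variable across samples. `covariance` uses the unbiased
#' (n-1) denominator; `spearman` uses average ranks for ties. Missing signal
#' values are handled pairwise per locus; loci with fewer than 3 complete
#' sample pairs for a target get a missing score (their count is reported in
#' a message).
#'
#' Metric guidance: methylation beta values are bounded in `[0, 1]`, so
#' covariance up-weights CpGs with larger methylation changes; count-like
#' accessibility peaks have incomparable ranges, so Pearson correlation puts
#' peaks on a common scale; Spearman suits monotone but nonlinear
#' relationships (ordinal targets). See [recommend_metric()].
#'
#' @param signal a [signal_matrix()].
#' @param targets a [target_variables()] (or samples x targets matrix with
#'   row names); sample sets must match the signal's.
#' @param metric `"covariance"`, `"pearson"` or `"spearman"`.
#' @return a [feature_contribution_scores()] with the signal's coords.
#' @examples
#' sm <- signal_matrix(data.frame(chrom = "chr1", start = 0:2, end = 1:3),
#'                     matrix(c(1, 2, 3, 0, 1, 0), 3, 2,
#'                            dimnames = list(NULL, c("s1", "s2"))) / 3)
#' tv <- target_variables(matrix(c(0, 1), 2, 1,
#'                               dimnames = list(c("s1", "s2"), "phenotype")))
#' compute_fcs(sm, tv, metric = "covariance")
#' @export
compute_fcs <- function(signal, targets,
                        metric = c("covariance", "pearson", "spearman")) {
  metric <- match.arg(metric)
  stopifnot(inherits(signal, "signal_matrix"))
  targets <- align_targets(signal, targets)
  X <- t(signal$values)                      # samples x loci
  Y <- targets$values                        # samples x targets
  if (nrow(X) < 3L) stop("need at least 3 samples")
  ysd <- apply(Y, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(ysd) & ysd == 0)) {
    if (metric == "covariance") {
      warning("constant target variable(s): covariance is 0 by definition")
    } else {
      stop("constant target variable(s): ", metric, " is undefined")
    }
  }
  vals <- fcs_values(X, Y, metric)
  fcs <- feature_contribution_scores(vals, coords = signal$coords,
                                     resolution = signal$resolution,
                                     metric = metric)
  n_missing <- sum(apply(is.na(fcs$values), 1L, all))
  if (n_missing > 0L) {
    message(n_missing, " locus/loci with missing scores ",
            "(fewer than 3 complete sample pairs or zero variance)")
  }
  fcs
}

# samples x loci, samples x targets -> loci x targets association matrix
fcs_values <- function(X, Y, metric) {
  vals <- switch(
    metric,
    covariance = stats::cov(X, Y, use = "pairwise.complete.obs"),
    pearson = suppressWarnings(
      stats::cor(X, Y, use = "pairwise.complete.obs")),
    spearman = suppressWarnings(
      stats::cor(X, Y, use = "pairwise.complete.obs", method = "spearman"))
  )
  # pairwise-complete counts; < 3 pairs -> missing score
  n_pair <- crossprod(!is.na(X), !is.na(Y))
  vals[n_pair < 3L] <- NA_real_
  if (metric != "covariance") vals[] <- pmin(1, pmax(-1, vals))
  rownames(vals) <- NULL
  vals
}

#' Derive unsupervised target variables by PCA
#'
#' Runs principal component analysis with samples as observations and loci
#' as variables, returning per-sample component scores as a target table.
#' The leading components capture the dominant axes of inter-sample
#' epigenetic covariation and can be annotated like any phenotype. Loci with
#' any missing value are dropped before the decomposition (count messaged).
#' Component signs are fixed by the convention that each component's
#' largest-magnitude loading is positive, so runs are reproducible.
#'
#' @param signal a [signal_matrix()].
#' @param n_components number of leading components to keep.
#' @param center center loci before decomposition (recommended, default on).
#' @param scale scale loci to unit variance: off is covariance-flavoured PCA
#'   (suits bounded methylation), on is correlation-flavoured (suits
#'   count-like accessibility).
#' @return a [target_variables()] with columns `PC1`, `PC2`, ...
#' @export
pca_targets <- function(signal, n_components, center = TRUE, scale = FALSE) {
  stopifnot(inherits(signal, "signal_matrix"))
  X <- t(signal$values)
  keep <- !apply(is.na(X), 2L, any)
  if (scale) keep <- keep & apply(X, 2L, stats::sd, na.rm = TRUE) > 0
  if (sum(!keep) > 0L) {
    message("dropping ", sum(!keep),
            " locus/loci with missing values", if (scale) " or zero variance",
            " before PCA")
  }
  X <- X[, keep, drop = FALSE]
  if (n_components > min(dim(X))) {
    stop("n_components exceeds min(samples, usable loci)")
  }
  fit <- stats::prcomp(X, center = center, scale. = scale)
  rank <- min(nrow(X) - as.integer(center), ncol(X))
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds the data rank (", rank, ")")
  }
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  load <- fit$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components),
                 function(j) sign(load[which.max(abs(load[, j])), j]),
                 numeric(1L))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, `*`)
  rownames(scores) <- sample_ids(signal)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  target_variables(scores)
}

#' Recommend an association metric
#'
#' Advisory defaults: covariance for bounded nucleotide-level signal
#' (methylation beta values), Pearson correlation for count-like
#' region-level signal (accessibility peaks), Spearman for ordinal targets
#' whatever the resolution. Never overrides an explicitly chosen metric.
#'
#' @param resolution `"nucleotide"` or `"region"`.
#' @param target_kind `"continuous"`, `"ordinal"` or `"latent_factor"`.
#' @return one of `"covariance"`, `"pearson"`, `"spearman"`.
#' @export
recommend_metric <- function(resolution = c("nucleotide", "region"),
                             target_kind = c("continuous", "ordinal",
                                             "latent_factor")) {
  resolution <- match.arg(resolution)
  target_kind <- match.arg(target_kind)
  if (target_kind == "ordinal") return("spearman")
  if (resolution == "nucleotide") "covariance" else "pearson"
}
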