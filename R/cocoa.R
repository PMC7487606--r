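#' Coordinate covariation analysis
#'
#' The main entry point: annotates inter-sample variation in an epigenetic
#' signal matrix with a database of region sets. The analysis proceeds in
#' two steps. Step 1 computes a feature contribution score (FCS) per locus
#' and target — the association (covariance, Pearson or Spearman) between
#' the locus signal and the target variable across samples; when no targets
#' are supplied, latent factors are derived internally by PCA and annotated
#' instead. Step 2 aggregates the FCS over every region set
#' ([score_region_set()]), filters sets with insufficient coverage, and
#' ranks the survivors. Significance comes from a sample-label permutation
#' test with region-set-specific null distributions ([build_null()]), a
#' gamma method-of-moments tail approximation (empirical fallback), and BH
#' FDR correction per target.
#'
#' A precomputed FCS matrix (e.g. CpG-by-latent-factor correlations from a
#' multi-omics factor analysis) can be supplied via `fcs`, skipping Step 1;
#' permutation inference is then unavailable, since the null requires
#' recomputing associations from raw signal under shuffled labels.
#'
#' @param signal a [signal_matrix()]. Ignored (may be `NULL`) when `fcs`
#'   is given.
#' @param targets a [target_variables()] (or samples x targets matrix with
#'   row names); `NULL` to derive PCA latent factors from the signal.
#' @param region_db a [region_set_db()].
#' @param fcs optional precomputed [feature_contribution_scores()].
#' @param metric `"auto"` picks [recommend_metric()]'s default for the
#'   signal resolution and target kind; or force `"covariance"`,
#'   `"pearson"`, `"spearman"`.
#' @param target_kind used by `metric = "auto"` for supplied targets:
#'   `"continuous"` or `"ordinal"`.
#' @param stat aggregation statistic at both levels of the
#'   nucleotide-resolution scorer: `"mean"` or `"median"`.
#' @param use_abs aggregate absolute FCS (default; see
#'   [score_region_set()]).
#' @param min_covered_regions coverage filter (default 100).
#' @param n_perm label permutations for inference; `0` skips inference.
#' @param p_method `"auto"` uses the gamma approximation where the fit is
#'   admissible and the empirical p-value otherwise; or force one source.
#' @param n_pcs number of PCA latent factors when `targets` is `NULL`.
#' @param center,scale PCA options (see [pca_targets()]); `scale = NULL`
#'   defaults to off for nucleotide (methylation-like) and on for region
#'   (count-like) signal.
#' @param seed integer seed for the permutation null.
#' @return object of class `cocoa`; see [print.cocoa()], [summary.cocoa()],
#'   [coef.cocoa()], [plot.cocoa()]. `$results` holds the ranked table with
#'   columns `region_set`, `target`, `score`, `n_regions_covered`,
#'   `n_features`, `p_value`, `q_value`, `p_source`, `rank`; `$null` the
#'   [build_null()] object.
#' @examples
#' sim <- default_planted_fixture(n_samples = 20, n_background_loci = 500,
#'                                n_planted_regions = 20, n_decoy_sets = 3,
#'                                decoy_regions_per_set = 20,
#'                                genome_length = 1e6)
#' fit <- cocoa(sim$signal, sim$targets, sim$db, min_covered_regions = 1,
#'              n_perm = 20, seed = 7)
#' head(fit$results)
#' @export
cocoa <- function(signal, targets = NULL, region_db, fcs = NULL,
                  metric = c("auto", "covariance", "pearson", "spearman"),
                  target_kind = c("continuous", "ordinal"),
                  stat = c("mean", "median"), use_abs = TRUE,
                  min_covered_regions = 100, n_perm = 300,
                  p_method = c("auto", "gamma", "empirical"),
                  n_pcs = 5, center = TRUE, scale = NULL, seed = 1) {
  metric <- match.arg(metric)
  target_kind <- match.arg(target_kind)
  stat <- match.arg(stat)
  p_method <- match.arg(p_method)
  cl <- match.call()

  if (is.null(fcs)) {
    stopifnot(inherits(signal, "signal_matrix"))
    if (is.null(targets)) {
      if (is.null(scale)) scale <- signal$resolution == "region"
      targets <- pca_targets(signal, n_pcs, center = center, scale = scale)
      kind <- "latent_factor"
    } else {
      kind <- target_kind
    }
    if (metric == "auto") metric <- recommend_metric(signal$resolution, kind)
    fcs <- compute_fcs(signal, targets, metric)
    can_infer <- TRUE
  } else {
    stopifnot(inherits(fcs, "feature_contribution_scores"))
    metric <- fcs$metric
    can_infer <- FALSE
    if (n_perm > 0) {
      message("precomputed FCS supplied: permutation inference skipped")
    }
  }

  results <- run_cocoa(fcs, region_db, stat = stat, use_abs = use_abs,
                       min_covered_regions = min_covered_regions)
  indices <- attr(results, "indices")
  null <- NULL
  results$p_source <- NA_character_

  if (can_infer && n_perm >= 1 && nrow(results) > 0L) {
    null <- build_null(signal, targets, db = NULL, metric = metric,
                       stat = stat, use_abs = use_abs, n_perm = n_perm,
                       seed = seed, indices = indices)
    for (i in seq_len(nrow(results))) {
      nm <- results$region_set[i]
      tg <- results$target[i]
      obs <- results$score[i]
      nulls_i <- null$scores[, nm, tg]
      g <- null$gamma[null$gamma$region_set == nm & null$gamma$target == tg, ]
      fit <- c(shape = g$shape[1L], scale = g$scale[1L])
      use_gamma <- switch(p_method,
                          auto = !is.na(fit[["shape"]]),
                          gamma = TRUE,
                          empirical = FALSE)
      if (use_gamma) {
        results$p_value[i] <- gamma_pvalue(fit, obs)
        results$p_source[i] <- "gamma"
      } else {
        results$p_value[i] <- empirical_pvalue(nulls_i, obs)
        results$p_source[i] <- "empirical"
      }
    }
    for (tg in unique(results$target)) {
      sel <- results$target == tg
      results$q_value[sel] <- adjust_fdr(results$p_value[sel])
    }
  }
  results <- rank_results(results)
  attr(results, "indices") <- NULL

  structure(
    list(results = results, null = null, fcs = fcs, targets = targets,
         region_db = region_db, metric = metric, stat = stat,
         use_abs = use_abs, min_covered_regions = min_covered_regions,
         n_perm = if (can_infer) n_perm else 0L, seed = seed,
         n_sets_total = length(region_db), call = cl),
    class = "cocoa"
  )
}

#' @describeIn cocoa compact display of the fitted analysis.
#' @param x,object a `cocoa` object.
#' @param ... unused.
#' @export
print.cocoa <- function(x, ...) {
  cat("Coordinate covariation analysis\n")
  cat("  metric: ", x$metric, ", stat: ", x$stat,
      ", abs FCS: ", x$use_abs, "\n", sep = "")
  cat("  region sets: ", length(unique(x$results$region_set)), " scored of ",
      x$n_sets_total, " (coverage filter >= ", x$min_covered_regions,
      ")\n", sep = "")
  cat("  targets: ", paste(unique(x$results$target), collapse = ", "),
      "\n", sep = "")
  if (x$n_perm > 0) {
    cat("  inference: ", x$n_perm, " label permutations (seed ", x$seed,
        ")\n", sep = "")
  } else {
    cat("  inference: none\n")
  }
  invisible(x)
}

#' @describeIn cocoa top-ranked region sets per target.
#' @param n_top rows shown per target.
#' @export
summary.cocoa <- function(object, n_top = 10L, ...) {
  res <- object$results
  out <- do.call(rbind, lapply(split(res, res$target), utils::head, n_top))
  rownames(out) <- NULL
  structure(list(top = out, n_top = n_top, fit = object),
            class = "summary.cocoa")
}

#' @export
print.summary.cocoa <- function(x, ...) {
  print(x$fit)
  cat("\nTop region sets per target:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @describeIn cocoa region set x target matrix of scores.
#' @export
coef.cocoa <- function(object, ...) {
  res <- object$results
  sets <- unique(res$region_set)
  tgts <- unique(res$target)
  m <- matrix(NA_real_, length(sets), length(tgts),
              dimnames = list(sets, tgts))
  m[cbind(match(res$region_set, sets), match(res$target, tgts))] <- res$score
  m
}

#' Plot a fitted analysis
#'
#' `type = "scores"` draws the ranked region-set scores for one target
#' (planted/top sets stand out as the high outliers); `type = "profile"`
#' draws the meta-region profile of one named region set.
#'
#' @param x a [cocoa()] object.
#' @param type `"scores"` or `"profile"`.
#' @param target target name or index.
#' @param region_set region set name (required for `type = "profile"`).
#' @param ... passed to the underlying plot.
#' @export
plot.cocoa <- function(x, type = c("scores", "profile"), target = 1L,
                       region_set = NULL, ...) {
  type <- match.arg(type)
  tgts <- unique(x$results$target)
  tg <- if (is.character(target)) target else tgts[target]
  if (type == "scores") {
    res <- x$results[x$results$target == tg, ]
    graphics::plot(res$rank, res$score, pch = 16, cex = 0.6,
                   xlab = "region set rank", ylab = "region set score",
                   main = tg, ...)
  } else {
    if (is.null(region_set)) stop("region_set is required for type='profile'")
    prof <- meta_region_profile(x$fcs, x$region_db$sets[[region_set]],
                                target = tg, use_abs = x$use_abs)
    plot(prof, ...)
  }
  invisible(x)
}
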