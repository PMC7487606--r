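# Permutation inference: region-set-specific null distributions from
# sample-label shuffling, gamma method-of-moments tail approximation with an
# empirical fallback, and BH FDR across the region sets tested.

#' Build region-set-specific null distributions
#'
#' For each permutation, the samples' target values are shuffled (one shared
#' permutation applied to all target columns jointly), the feature
#' contribution scores are recomputed, and every region set is rescored.
#' The epigenetic matrix itself is never shuffled, so each null preserves
#' the inter-locus correlation structure and the coverage profile of its
#' region set. A gamma distribution is fitted to each null by the method of
#' moments where admissible (all scores nonnegative, positive variance).
#'
#' When the signal and targets are complete (no missing values) all
#' permutations are computed in a handful of matrix products; otherwise the
#' association step is repeated per permutation.
#'
#' @inheritParams compute_fcs
#' @inheritParams run_cocoa
#' @param n_perm number of label permutations (default 300; the gamma
#'   approximation extrapolates the tail beyond `1/n_perm`).
#' @param seed integer seed; the whole null is reproducible from it.
#' @param indices optional precomputed overlap indices (the `"indices"`
#'   attribute of a [run_cocoa()] result); when omitted they are computed
#'   from `db` with the same coverage filter.
#' @return object of class `cocoa_null`: a list with `scores`, an array of
#'   dimension `n_perm` x sets x targets, and `gamma`, a data.frame of
#'   method-of-moments `shape`/`scale` per (set, target) (`NA` where the fit
#'   was refused).
#' @export
build_null <- function(signal, targets, db,
                       metric = c("covariance", "pearson", "spearman"),
                       stat = c("mean", "median"), use_abs = TRUE,
                       min_covered_regions = 100, n_perm = 300, seed = 1,
                       indices = NULL) {
  metric <- match.arg(metric)
  stat <- match.arg(stat)
  stopifnot(inherits(signal, "signal_matrix"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  targets <- align_targets(signal, targets)
  if (is.null(indices)) {
    stopifnot(inherits(db, "region_set_db"))
    indices <- lapply(db$sets, function(rs) overlap_index(signal$coords, rs))
    covered <- vapply(indices, `[[`, numeric(1L), "n_regions_covered")
    indices <- indices[covered >= min_covered_regions]
  }
  if (length(indices) == 0L) stop("no region sets to build nulls for")
  S <- ncol(signal$values)
  Tn <- colnames(targets$values)
  K <- length(Tn)
  set.seed(seed)
  perms <- vapply(seq_len(n_perm), function(i) sample.int(S), integer(S))

  scores <- array(NA_real_,
                  dim = c(n_perm, length(indices), K),
                  dimnames = list(NULL, names(indices), Tn))
  complete <- !anyNA(signal$values) && !anyNA(targets$values)
  if (complete) {
    # rank-transform once for spearman (ranks are permutation-equivariant),
    # then every permutation is a column of one cross-product
    X <- signal$values
    Y <- targets$values
    if (metric == "spearman") {
      X <- t(apply(X, 1L, rank))
      Y <- apply(Y, 2L, rank)
    }
    Xc <- X - rowMeans(X)
    if (metric != "covariance") {
      xsd <- sqrt(rowSums(Xc^2) / (S - 1))
      xsd[xsd == 0] <- NA_real_
      Xc <- Xc / xsd
    }
    Yc <- sweep(Y, 2L, colMeans(Y))
    if (metric != "covariance") {
      Yc <- sweep(Yc, 2L, sqrt(colSums(Yc^2) / (S - 1)), `/`)
    }
    chunk <- max(1L, 262144L %/% max(1L, nrow(X)) %/% K * 16L)
    for (lo in seq(1L, n_perm, by = chunk)) {
      hi <- min(lo + chunk - 1L, n_perm)
      block <- hi - lo + 1L
      ZP <- matrix(0, nrow = S, ncol = K * block)
      for (b in seq_len(block)) {
        ZP[, (b - 1L) * K + seq_len(K)] <- Yc[perms[, lo + b - 1L], ,
                                              drop = FALSE]
      }
      FCS <- Xc %*% ZP / (S - 1)
      if (metric != "covariance") FCS[] <- pmin(1, pmax(-1, FCS))
      colnames(FCS) <- rep(Tn, block)
      for (si in seq_along(indices)) {
        s <- score_from_index(FCS, indices[[si]], signal$resolution, stat,
                              use_abs)
        scores[lo:hi, si, ] <- matrix(s, ncol = K, byrow = TRUE)
      }
    }
  } else {
    X <- t(signal$values)
    for (p in seq_len(n_perm)) {
      Yp <- targets$values[perms[, p], , drop = FALSE]
      FCS <- fcs_values(X, Yp, metric)
      colnames(FCS) <- Tn
      for (si in seq_along(indices)) {
        scores[p, si, ] <- score_from_index(FCS, indices[[si]],
                                            signal$resolution, stat, use_abs)
      }
    }
  }

  gamma <- do.call(rbind, lapply(names(indices), function(nm) {
    do.call(rbind, lapply(Tn, function(tg) {
      fit <- fit_gamma_mom(scores[, nm, tg])
      data.frame(region_set = nm, target = tg,
                 shape = fit[["shape"]], scale = fit[["scale"]])
    }))
  }))
  rownames(gamma) <- NULL
  structure(
    list(scores = scores, gamma = gamma, n_perm = n_perm, seed = seed,
         metric = metric, stat = stat, use_abs = use_abs),
    class = "cocoa_null"
  )
}

#' @export
print.cocoa_null <- function(x, ...) {
  d <- dim(x$scores)
  cat("<cocoa_null> ", d[1L], " permutations x ", d[2L], " region sets x ",
      d[3L], " target(s); gamma fit for ",
      sum(!is.na(x$gamma$shape)), "/", nrow(x$gamma), " nulls\n", sep = "")
  invisible(x)
}

#' Gamma fit by the method of moments
#'
#' `shape = mean^2 / var`, `scale = var / mean`, with the unbiased sample
#' variance. The fit is refused — both parameters returned as `NA` — when
#' any score is negative (the gamma support is nonnegative; signed scoring
#' falls back to the empirical p-value rather than guessing a shift), when
#' any score is missing, or when the variance is zero.
#'
#' @param scores numeric vector of null scores.
#' @return named numeric vector `c(shape=, scale=)`.
#' @examples
#' fit_gamma_mom(c(1, 2, 3))   # mean 2, var 1 -> shape 4, scale 0.5
#' @export
fit_gamma_mom <- function(scores) {
  refused <- c(shape = NA_real_, scale = NA_real_)
  if (length(scores) < 2L || anyNA(scores) || any(scores < 0)) return(refused)
  m <- mean(scores)
  v <- stats::var(scores)
  if (!is.finite(m) || !is.finite(v) || v <= 0 || m <= 0) return(refused)
  c(shape = m^2 / v, scale = v / m)
}

#' Upper-tail gamma p-value
#'
#' p = P(Gamma(shape, scale) >= observed). The approximation extrapolates
#' the tail beyond the permutation count; it is accurate for high p-values
#' but may overstate the significance of very small ones, so small gamma
#' p-values are best read as a screen, not an exact tail probability.
#'
#' @param fit named vector from [fit_gamma_mom()].
#' @param observed observed score.
#' @return p-value in (0, 1].
#' @export
gamma_pvalue <- function(fit, observed) {
  shape <- fit[["shape"]]
  scale <- fit[["scale"]]
  if (is.na(shape) || is.na(scale)) return(NA_real_)
  if (is.na(observed)) return(NA_real_)
  if (observed < 0) {
    warning("observed score below the gamma support; p = 1")
    return(1)
  }
  p <- stats::pgamma(observed, shape = shape, scale = scale,
                     lower.tail = FALSE)
  max(p, .Machine$double.xmin)
}

#' Empirical permutation p-value
#'
#' Add-one convention: `p = (1 + #\{null >= observed\}) / (1 + n_perm)`,
#' so p is never zero (a finite permutation count cannot resolve smaller
#' tails). Ties count as exceedances.
#'
#' @param null_scores numeric vector of null scores.
#' @param observed observed score.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(null_scores, observed) {
  null_scores <- null_scores[!is.na(null_scores)]
  if (length(null_scores) == 0L) stop("need at least one null score")
  if (is.na(observed)) return(NA_real_)
  (1 + sum(null_scores >= observed)) / (1 + length(null_scores))
}

#' Benjamini-Hochberg q-values
#'
#' Standard BH step-up adjustment across the region sets tested (applied per
#' target). Missing p-values propagate to missing q-values and do not count
#' toward the number of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}
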