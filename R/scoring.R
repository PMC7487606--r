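# Step 2: aggregate feature contribution scores over region sets.
#
# Nucleotide-resolution signal uses nested averaging: per region, the stat of
# the FCS of overlapping loci; per set, the same stat over the per-region
# values. Region-resolution signal uses an overlap-proportion-weighted
# average: each (data region d, set region r) overlap contributes FCS(d) with
# weight overlap(d, r) / width(r).

# Precompute the overlap structure between a coordinate table and one region
# set; scoring any FCS column (observed or permuted) is then a cheap
# aggregation over this index.
overlap_index <- function(coords, rset) {
  stopifnot(inherits(rset, "region_set"))
  ov <- find_overlaps(coords, rset$regions)
  list(
    locus = ov$query,
    region = ov$subject,
    weight = ov$width / (rset$regions$end - rset$regions$start)[ov$subject],
    n_regions_covered = length(unique(ov$subject)),
    n_features = length(unique(ov$query)),
    n_set_regions = nrow(rset$regions)
  )
}

# FCS matrix (loci x K columns) + index -> score vector of length K.
# Missing FCS values are excluded at the innermost level.
score_from_index <- function(fcs_mat, idx, resolution, stat = "mean",
                             use_abs = TRUE) {
  K <- ncol(fcs_mat)
  if (length(idx$locus) == 0L) {
    return(stats::setNames(rep(NA_real_, K), colnames(fcs_mat)))
  }
  F <- fcs_mat[idx$locus, , drop = FALSE]
  if (use_abs) F <- abs(F)
  ok <- !is.na(F)
  if (resolution == "region") {
    F0 <- F
    F0[!ok] <- 0
    numer <- colSums(idx$weight * F0)
    denom <- colSums(idx$weight * ok)
    score <- ifelse(denom > 0, numer / denom, NA_real_)
  } else if (stat == "mean") {
    F0 <- F
    F0[!ok] <- 0
    sums <- rowsum(F0, idx$region, reorder = FALSE)
    cnts <- rowsum(ok + 0, idx$region, reorder = FALSE)
    region_means <- sums / cnts          # NaN where a region has only NA FCS
    region_means[cnts == 0] <- NA_real_
    score <- colMeans(region_means, na.rm = TRUE)
    score[is.nan(score)] <- NA_real_
  } else {                               # median at both levels
    by_region <- split(seq_along(idx$region), idx$region)
    region_stats <- vapply(by_region, function(rows) {
      apply(F[rows, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    }, numeric(K))
    region_stats <- matrix(region_stats, nrow = K)  # K x n_regions
    score <- apply(region_stats, 1L, stats::median, na.rm = TRUE)
    score[is.nan(score)] <- NA_real_
  }
  stats::setNames(as.numeric(score), colnames(fcs_mat))
}

#' Score one region set
#'
#' Aggregates feature contribution scores over a region set into one COCOA
#' score per target. At nucleotide resolution the FCS of loci overlapping
#' each region are combined with `stat`, and the per-region values are
#' combined with the same `stat` (regions containing no locus are excluded;
#' a locus inside two regions contributes to both). At region resolution
#' every (data region, set region) overlap contributes the data region's FCS
#' weighted by the proportion of the set region it covers, and the score is
#' the weighted average. With `use_abs` the absolute FCS are aggregated —
#' the default, since latent-factor loading signs are arbitrary and
#' methylation shifts in either direction are equally informative.
#'
#' @param fcs a [feature_contribution_scores()] carrying coords.
#' @param rset a [region_set()].
#' @param stat `"mean"` or `"median"`, applied at both aggregation levels
#'   (nucleotide resolution only).
#' @param use_abs aggregate absolute FCS values.
#' @return data.frame with one row per target: `region_set`, `target`,
#'   `score` (missing when the set has no coverage), `n_regions_covered`
#'   (set regions containing at least one locus), `n_features` (distinct
#'   loci overlapping the set).
#' @export
score_region_set <- function(fcs, rset, stat = c("mean", "median"),
                             use_abs = TRUE) {
  stat <- match.arg(stat)
  stopifnot(inherits(fcs, "feature_contribution_scores"))
  if (is.null(fcs$coords)) stop("fcs must carry locus coordinates")
  idx <- overlap_index(fcs$coords, rset)
  score <- score_from_index(fcs$values, idx, fcs$resolution, stat,
                            use_abs = use_abs && !fcs$abs_applied)
  data.frame(
    region_set = rset$name,
    target = colnames(fcs$values),
    score = as.numeric(score),
    n_regions_covered = idx$n_regions_covered,
    n_features = idx$n_features,
    row.names = NULL
  )
}

#' Score and rank a region set database
#'
#' Scores every (region set, target) pair, drops region sets with fewer than
#' `min_covered_regions` regions covered by the data (the paper-default
#' threshold of 100 protects against unstable scores from sparsely assayed
#' sets), and ranks the survivors per target by descending score with ties
#' broken by region set name.
#'
#' @inheritParams score_region_set
#' @param db a [region_set_db()].
#' @param min_covered_regions minimum covered-region count for a set to be
#'   reported.
#' @return ranked data.frame with columns `region_set`, `target`, `score`,
#'   `n_regions_covered`, `n_features`, `p_value`, `q_value` (both `NA`
#'   until permutation inference is run, see [cocoa()]), `rank`. The
#'   precomputed overlap indices of surviving sets are attached as attribute
#'   `"indices"` for reuse by [build_null()].
#' @export
run_cocoa <- function(fcs, db, stat = c("mean", "median"), use_abs = TRUE,
                      min_covered_regions = 100) {
  stat <- match.arg(stat)
  stopifnot(inherits(fcs, "feature_contribution_scores"),
            inherits(db, "region_set_db"))
  if (is.null(fcs$coords)) stop("fcs must carry locus coordinates")
  indices <- lapply(db$sets, function(rs) overlap_index(fcs$coords, rs))
  covered <- vapply(indices, `[[`, numeric(1L), "n_regions_covered")
  keep <- covered >= min_covered_regions
  if (any(!keep)) {
    message(sum(!keep), " region set(s) dropped with < ", min_covered_regions,
            " covered regions: ",
            paste(utils::head(names(indices)[!keep], 5L), collapse = ", "),
        if (sum(!keep) > 5L) ", ..." else "")
  }
  if (!any(keep)) {
    warning("all region sets filtered out")
    out <- data.frame(region_set = character(), target = character(),
                      score = numeric(), n_regions_covered = integer(),
                      n_features = integer(), p_value = numeric(),
                      q_value = numeric(), rank = integer())
    attr(out, "indices") <- list()
    return(out)
  }
  abs_eff <- use_abs && !fcs$abs_applied
  rows <- lapply(names(indices)[keep], function(nm) {
    idx <- indices[[nm]]
    score <- score_from_index(fcs$values, idx, fcs$resolution, stat, abs_eff)
    data.frame(region_set = nm, target = colnames(fcs$values),
               score = as.numeric(score),
               n_regions_covered = idx$n_regions_covered,
               n_features = idx$n_features, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_value <- NA_real_
  out$q_value <- NA_real_
  out <- rank_results(out)
  attr(out, "indices") <- indices[keep]
  out
}

#' Per-sample average signal over a region set
#'
#' For each sample, the signal of the loci overlapping each region is
#' averaged, and the per-region averages are averaged — so every covered
#' region carries equal weight regardless of how many loci it contains.
#' Used to summarise a region set's raw epigenetic signal per sample (for
#' example, mean methylation of a factor's binding sites for downstream
#' validation models).
#'
#' @param signal a [signal_matrix()].
#' @param rset a [region_set()].
#' @return named numeric vector, one value per sample (all missing when the
#'   set has no coverage).
#' @export
region_set_signal_average <- function(signal, rset) {
  stopifnot(inherits(signal, "signal_matrix"))
  idx <- overlap_index(signal$coords, rset)
  if (length(idx$locus) == 0L) {
    return(stats::setNames(rep(NA_real_, ncol(signal$values)),
                           sample_ids(signal)))
  }
  V <- signal$values[idx$locus, , drop = FALSE]
  ok <- !is.na(V)
  V[!ok] <- 0
  sums <- rowsum(V, idx$region, reorder = FALSE)
  cnts <- rowsum(ok + 0, idx$region, reorder = FALSE)
  region_means <- sums / cnts
  region_means[cnts == 0] <- NA_real_
  out <- colMeans(region_means, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  stats::setNames(out, sample_ids(signal))
}
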