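# Meta-region profiles: how specific is the captured covariation to a region
# set, relative to its flanking genome? Each region is expanded to a fixed
# window centered on its midpoint, the window is cut into bins, per-region
# bin values are computed with the same aggregation as the COCOA score, and
# corresponding bins are averaged across regions.

#' Compute a meta-region FCS profile
#'
#' Every region of the set is replaced by a window of `total_width` bases
#' centered on the region midpoint (`floor((start + end) / 2)`), cut into
#' `n_bins` contiguous bins of approximately equal width (integer
#' boundaries by rounding, total coverage preserved; `n_bins` is odd so
#' offset 0 labels the middle bin). At nucleotide resolution a bin's
#' per-region value is the `stat` of the FCS of loci whose midpoints fall in
#' the bin; at region resolution it is the overlap-proportion-weighted
#' average of data regions against the bin. The final profile averages each
#' bin over the regions that have any datum in it. A central peak indicates
#' covariation specific to the region set rather than its neighbourhood.
#'
#' @inheritParams score_region_set
#' @param target FCS column to profile (name or index).
#' @param total_width window width in bases (default 14000, i.e. regions
#'   expanded to 14 kb).
#' @param n_bins odd number of bins (default 21).
#' @return object of class `meta_region_profile` with fields `bin_offsets`
#'   (signed base offsets of bin centers from the region center),
#'   `bin_values`, `bins_n_regions`, `region_set`, `target`, `total_width`.
#' @export
meta_region_profile <- function(fcs, rset, target = 1L, total_width = 14000,
                                n_bins = 21, stat = c("mean", "median"),
                                use_abs = TRUE) {
  stat <- match.arg(stat)
  stopifnot(inherits(fcs, "feature_contribution_scores"),
            inherits(rset, "region_set"))
  if (is.null(fcs$coords)) stop("fcs must carry locus coordinates")
  if (nrow(rset$regions) == 0L) stop("empty region set")
  if (n_bins < 3L || n_bins %% 2L == 0L) stop("n_bins must be odd and >= 3")
  f <- fcs$values[, target]
  if (use_abs && !fcs$abs_applied) f <- abs(f)
  tname <- if (is.character(target)) target else colnames(fcs$values)[target]

  regions <- rset$regions
  wide <- (regions$end - regions$start) > total_width
  if (any(wide)) {
    warning(sum(wide), " region(s) wider than total_width skipped")
    regions <- regions[!wide, , drop = FALSE]
    if (nrow(regions) == 0L) stop("no regions narrower than total_width")
  }
  center <- floor((regions$start + regions$end) / 2)
  ws <- center - floor(total_width / 2)           # window start (may be < 0)
  rb <- round(seq_len(n_bins + 1L) * total_width / n_bins -
                total_width / n_bins)             # relative boundaries, rb[1]=0
  offsets <- (rb[-1L] + rb[-(n_bins + 1L)]) / 2 - total_width / 2

  # overlap query uses windows clipped at 0; bin arithmetic keeps raw ws
  windows <- data.frame(chrom = regions$chrom, start = pmax(ws, 0),
                        end = ws + total_width)
  acc_sum <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  acc_w <- matrix(0, nrow = nrow(regions), ncol = n_bins)
  if (fcs$resolution == "nucleotide") {
    mids <- floor((fcs$coords$start + fcs$coords$end) / 2)
    pts <- data.frame(chrom = fcs$coords$chrom, start = mids, end = mids + 1)
    ov <- find_overlaps(windows, pts)
    if (nrow(ov)) {
      off <- mids[ov$subject] - ws[ov$query]
      inside <- off >= 0 & off < total_width
      ov <- ov[inside, , drop = FALSE]; off <- off[inside]
      bin <- findInterval(off, rb)
      fo <- f[ov$subject]
      keep <- !is.na(fo)
      # column-major linear index of matrix cell [region, bin]
      key <- (bin[keep] - 1L) * nrow(regions) + ov$query[keep]
      if (stat == "median") {
        med <- tapply(fo[keep], key, stats::median)
        acc_sum[as.integer(names(med))] <- med
        acc_w[as.integer(names(med))] <- 1
      } else {
        sums <- rowsum(fo[keep], key)
        cnts <- rowsum(rep(1, sum(keep)), key)
        cells <- as.integer(rownames(sums))
        acc_sum[cells] <- sums[, 1L]
        acc_w[cells] <- cnts[, 1L]
      }
    }
  } else {
    ov <- find_overlaps(windows, fcs$coords)
    if (nrow(ov)) {
      for (k in seq_len(nrow(ov))) {
        r <- ov$query[k]; d <- ov$subject[k]
        fo <- f[d]
        if (is.na(fo)) next
        ds <- max(fcs$coords$start[d], ws[r])
        de <- min(fcs$coords$end[d], ws[r] + total_width)
        b_lo <- findInterval(ds - ws[r], rb)
        b_hi <- findInterval(de - 1 - ws[r], rb)
        for (b in b_lo:b_hi) {
          ovl <- min(de, ws[r] + rb[b + 1L]) - max(ds, ws[r] + rb[b])
          if (ovl <= 0) next
          w <- ovl / (rb[b + 1L] - rb[b])
          acc_sum[r, b] <- acc_sum[r, b] + w * fo
          acc_w[r, b] <- acc_w[r, b] + w
        }
      }
    }
  }
  region_bin <- acc_sum / acc_w                  # NaN where no datum
  region_bin[acc_w == 0] <- NA_real_
  bin_values <- colMeans(region_bin, na.rm = TRUE)
  bin_values[is.nan(bin_values)] <- NA_real_
  structure(
    list(bin_offsets = offsets, bin_values = bin_values,
         bins_n_regions = colSums(!is.na(region_bin)),
         region_set = rset$name, target = tname, total_width = total_width,
         n_bins = n_bins),
    class = "meta_region_profile"
  )
}

#' Center-enrichment statistic of a meta-region profile
#'
#' Center-bin value minus the mean of the `flank_bins` outermost bins on
#' each side. Positive values indicate covariation enriched at the regions
#' themselves relative to the flanking genome.
#'
#' @param profile a [meta_region_profile()].
#' @param flank_bins number of outermost bins per side used as the flank
#'   baseline (must be smaller than half the bin count).
#' @return numeric; missing if the center bin is empty.
#' @export
profile_peak_statistic <- function(profile, flank_bins = 2L) {
  stopifnot(inherits(profile, "meta_region_profile"))
  n <- profile$n_bins
  if (flank_bins < 1L || flank_bins >= n / 2) {
    stop("flank_bins must be in [1, n_bins/2)")
  }
  center <- profile$bin_values[(n + 1L) %/% 2L]
  if (is.na(center)) return(NA_real_)
  flank <- profile$bin_values[c(seq_len(flank_bins),
                                n - seq_len(flank_bins) + 1L)]
  center - mean(flank, na.rm = TRUE)
}

#' @export
print.meta_region_profile <- function(x, ...) {
  cat("<meta_region_profile> ", x$region_set, " / ", x$target, ": ",
      x$n_bins, " bins over ", x$total_width, " bp; center value ",
      format(x$bin_values[(x$n_bins + 1L) %/% 2L], digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Plot a meta-region profile
#'
#' Line plot of average FCS per bin against the signed offset from the
#' region center, with the center marked.
#'
#' @param x a [meta_region_profile()].
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.meta_region_profile <- function(x, ...) {
  graphics::plot(x$bin_offsets, x$bin_values, type = "b", pch = 16,
                 xlab = "offset from region center (bp)",
                 ylab = "average feature contribution score",
                 main = paste0(x$region_set, " / ", x$target), ...)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  invisible(x)
}

#' Write a meta-region profile as a TSV
#'
#' @param profile a [meta_region_profile()].
#' @param path output path.
#' @export
write_meta_region_profile <- function(profile, path) {
  utils::write.table(
    data.frame(bin_offset = profile$bin_offsets,
               value = profile$bin_values,
               n_regions = profile$bins_n_regions),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
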