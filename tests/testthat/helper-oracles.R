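# Independent brute-force oracles (quadratic scans, per-base masks) and
# small random-instance generators. These deliberately share no code with
# the package internals they check.

# all overlapping (query, subject) pairs by scanning every pair
oracle_overlaps <- function(query, subject) {
  out <- NULL
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      lo <- max(query$start[i], subject$start[j])
      hi <- min(query$end[i], subject$end[j])
      if (lo < hi) out <- rbind(out, c(i, j, hi - lo))
    }
  }
  if (is.null(out)) {
    return(data.frame(query = integer(), subject = integer(),
                      width = numeric()))
  }
  data.frame(query = out[, 1], subject = out[, 2], width = out[, 3])
}

# covered bases on one chromosome via a per-position boolean mask
oracle_covered_bases <- function(regions, max_pos = 1e4) {
  mask <- logical(max_pos)
  for (i in seq_len(nrow(regions))) {
    mask[(regions$start[i] + 1):regions$end[i]] <- TRUE
  }
  sum(mask)
}

# nucleotide scorer: per region, stat of |FCS| of overlapping loci; per set,
# the same stat over covered regions
oracle_score_nucleotide <- function(coords, fvec, regions, stat = "mean",
                                    use_abs = TRUE) {
  if (use_abs) fvec <- abs(fvec)
  agg <- if (stat == "mean") mean else median
  per_region <- c()
  for (j in seq_len(nrow(regions))) {
    vals <- c()
    for (i in seq_len(nrow(coords))) {
      if (coords$chrom[i] == regions$chrom[j] &&
          max(coords$start[i], regions$start[j]) <
            min(coords$end[i], regions$end[j])) {
        vals <- c(vals, fvec[i])
      }
    }
    vals <- vals[!is.na(vals)]
    if (length(vals)) per_region <- c(per_region, agg(vals))
  }
  if (length(per_region) == 0) NA_real_ else agg(per_region)
}

# weighted scorer: one term per (data region, set region) overlap with
# weight overlap / width(set region)
oracle_score_weighted <- function(coords, fvec, regions, use_abs = TRUE) {
  if (use_abs) fvec <- abs(fvec)
  num <- 0; den <- 0
  for (i in seq_len(nrow(coords))) {
    if (is.na(fvec[i])) next
    for (j in seq_len(nrow(regions))) {
      if (coords$chrom[i] != regions$chrom[j]) next
      ovl <- min(coords$end[i], regions$end[j]) -
        max(coords$start[i], regions$start[j])
      if (ovl <= 0) next
      w <- ovl / (regions$end[j] - regions$start[j])
      num <- num + w * fvec[i]
      den <- den + w
    }
  }
  if (den == 0) NA_real_ else num / den
}

# per-sample nested-mean signal average over a region set
oracle_signal_average <- function(coords, values, regions) {
  out <- rep(NA_real_, ncol(values))
  for (s in seq_len(ncol(values))) {
    per_region <- c()
    for (j in seq_len(nrow(regions))) {
      vals <- c()
      for (i in seq_len(nrow(coords))) {
        if (coords$chrom[i] == regions$chrom[j] &&
            max(coords$start[i], regions$start[j]) <
              min(coords$end[i], regions$end[j])) {
          vals <- c(vals, values[i, s])
        }
      }
      vals <- vals[!is.na(vals)]
      if (length(vals)) per_region <- c(per_region, mean(vals))
    }
    if (length(per_region)) out[s] <- mean(per_region)
  }
  out
}

random_regions <- function(n, chroms = "chr1", max_pos = 1000,
                           max_width = 60) {
  start <- sample.int(max_pos - max_width, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE))
}

# tiny helper: single-base locus table
point_loci <- function(pos, chrom = "chr1") {
  data.frame(chrom = chrom, start = pos, end = pos + 1)
}

make_signal <- function(coords, values, resolution = "nucleotide") {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  signal_matrix(coords, values, resolution = resolution)
}

make_fcs <- function(coords, fvec, resolution = "nucleotide",
                     name = "t1") {
  feature_contribution_scores(
    matrix(fvec, ncol = 1, dimnames = list(NULL, name)),
    coords = coords, resolution = resolution, metric = "pearson")
}
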