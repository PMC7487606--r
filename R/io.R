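# Readers/writers: BED region sets, signal/target/FCS tables, result tables.
# Chromosome names are matched by exact string equality throughout; the
# normalize_chrom flag (adds a "chr" prefix to bare names at read time) is the
# only aliasing the package ever performs, and only when asked.

norm_chrom <- function(chrom, normalize) {
  if (!normalize) return(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Read a BED file as a region set
#'
#' Columns 1-3 (chrom, start, end; 0-based half-open) are used; further
#' columns are ignored. `track`, `browser` and `#` comment lines are skipped.
#'
#' @param path BED file path.
#' @param name region set name; defaults to the file stem.
#' @param normalize_chrom prefix bare chromosome names with `"chr"`.
#' @return a [region_set()].
#' @export
read_bed <- function(path, name = NULL, normalize_chrom = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  keep <- which(!skip)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (length(keep) == 0L) return(region_set(name, empty_regions()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 3L)) {
    stop("malformed BED line ", keep[which(nfield < 3L)[1L]], " in ", path,
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end) |
    start < 0 | end <= start
  if (any(bad)) {
    stop("malformed BED line ", keep[which(bad)[1L]], " in ", path,
         ": coordinates must be integers with end > start >= 0")
  }
  region_set(name, data.frame(chrom = norm_chrom(chrom, normalize_chrom),
                              start = start, end = end,
                              stringsAsFactors = FALSE))
}

empty_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric())
}

#' Load a directory of BED files as a region set database
#'
#' One region set per `.bed` file, in sorted filename order (independent of
#' filesystem listing order). An optional annotation sheet — a TSV/CSV with a
#' `filename` column — contributes free-form metadata to the matching sets;
#' rows naming no present file are skipped with a warning.
#'
#' @param dir directory containing `.bed` files.
#' @param annotation optional path to the annotation sheet.
#' @param genome assembly label stored on the database (informational).
#' @param normalize_chrom passed to [read_bed()].
#' @return a [region_set_db()].
#' @export
load_region_db <- function(dir, annotation = NULL, genome = NA_character_,
                           normalize_chrom = FALSE) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(files) == 0L) stop("no .bed files in ", dir)
  sets <- lapply(files, read_bed, normalize_chrom = normalize_chrom)
  db <- region_set_db(sets, genome = genome)
  if (!is.null(annotation)) {
    sep <- if (grepl("\\.csv$", annotation)) "," else "\t"
    sheet <- utils::read.table(annotation, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, check.names = FALSE)
    if (!"filename" %in% names(sheet)) {
      stop("annotation sheet needs a 'filename' column")
    }
    stems <- sub("\\.[^.]*$", "", sheet$filename)
    known <- stems %in% names(db$sets)
    if (any(!known)) {
      warning("annotation rows with no matching BED file skipped: ",
              paste(sheet$filename[!known], collapse = ", "))
    }
    for (i in which(known)) {
      meta <- as.list(sheet[i, setdiff(names(sheet), "filename"), drop = FALSE])
      db$sets[[stems[i]]]$metadata <- meta
    }
  }
  db
}

#' Read a signal matrix from a delimited table
#'
#' Tab-delimited with a header row. At region resolution the first three
#' columns are `chrom`, `start`, `end` (0-based half-open); at nucleotide
#' resolution the first two are `chrom` and a position column (1-based by
#' default, converted internally to a `[p-1, p)` interval). All remaining
#' columns are per-sample signal values; non-numeric cells become missing.
#'
#' @param path file path.
#' @param resolution `"nucleotide"` or `"region"`.
#' @param one_based at nucleotide resolution, whether positions are 1-based.
#' @param methylation passed to [signal_matrix()].
#' @param normalize_chrom prefix bare chromosome names with `"chr"`.
#' @return a [signal_matrix()].
#' @export
read_signal_matrix <- function(path, resolution = c("nucleotide", "region"),
                               one_based = TRUE, methylation = FALSE,
                               normalize_chrom = FALSE) {
  resolution <- match.arg(resolution)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  ncoord <- if (resolution == "region") 3L else 2L
  if (ncol(tab) <= ncoord) stop("no sample columns in ", path)
  sample_cols <- names(tab)[(ncoord + 1L):ncol(tab)]
  if (anyDuplicated(sample_cols)) {
    stop("duplicate sample column names in ", path, ": ",
         paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", "))
  }
  chrom <- norm_chrom(as.character(tab[[1L]]), normalize_chrom)
  if (resolution == "region") {
    coords <- data.frame(chrom = chrom, start = tab[[2L]], end = tab[[3L]])
  } else {
    pos <- as.numeric(tab[[2L]])
    start <- if (one_based) pos - 1 else pos
    coords <- data.frame(chrom = chrom, start = start, end = start + 1)
  }
  values <- vapply(tab[sample_cols],
                   function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(tab)))
  values <- matrix(values, nrow = nrow(tab),
                   dimnames = list(NULL, sample_cols))
  signal_matrix(coords, values, resolution = resolution,
                methylation = methylation)
}

#' Write a signal matrix to a delimited table
#'
#' Inverse of [read_signal_matrix()]: nucleotide-resolution matrices are
#' written as `chrom`/`pos` (1-based), region-resolution as
#' `chrom`/`start`/`end`.
#'
#' @param signal a [signal_matrix()].
#' @param path output path.
#' @export
write_signal_matrix <- function(signal, path) {
  stopifnot(inherits(signal, "signal_matrix"))
  if (signal$resolution == "nucleotide") {
    head <- data.frame(chrom = signal$coords$chrom,
                       pos = signal$coords$start + 1)
  } else {
    head <- signal$coords
  }
  tab <- cbind(head, as.data.frame(signal$values))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-variable table
#'
#' Tab-delimited with a header; the first column holds sample ids, every
#' further column one target variable.
#'
#' @param path file path.
#' @return a [target_variables()].
#' @export
read_target_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("target table needs sample ids plus >= 1 target")
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- as.character(tab[[1L]])
  target_variables(values)
}

#' @rdname read_target_table
#' @param targets a [target_variables()] to write.
#' @export
write_target_table <- function(targets, path) {
  stopifnot(inherits(targets, "target_variables"))
  tab <- cbind(data.frame(sample_id = rownames(targets$values)),
               as.data.frame(targets$values))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a precomputed feature contribution score matrix
#'
#' For workflows where per-locus association scores with each target were
#' computed elsewhere (e.g. CpG-by-latent-factor correlations from a
#' multi-omics factor analysis), the scoring step can consume them directly,
#' skipping the association step. The table layout matches
#' [read_signal_matrix()], with target names as the value columns.
#'
#' @inheritParams read_signal_matrix
#' @return a `feature_contribution_scores` object (see [compute_fcs()]).
#' @export
read_fcs_matrix <- function(path, resolution = c("nucleotide", "region"),
                            one_based = TRUE, normalize_chrom = FALSE) {
  resolution <- match.arg(resolution)
  sm <- read_signal_matrix(path, resolution = resolution,
                           one_based = one_based,
                           normalize_chrom = normalize_chrom)
  feature_contribution_scores(sm$values, coords = sm$coords,
                              resolution = resolution,
                              metric = "precomputed")
}

#' Write a ranked region-set result table
#'
#' Tab-delimited columns `region_set`, `target`, `score`,
#' `n_regions_covered`, `n_features`, `p_value`, `q_value`, `rank`
#' (plus `p_source` when present), sorted per target by descending score
#' with ties broken by region set name.
#'
#' @param results result data.frame from [run_cocoa()] or [cocoa()].
#' @param path output path.
#' @export
write_results <- function(results, path) {
  cols <- c("region_set", "target", "score", "n_regions_covered",
            "n_features", "p_value", "q_value", "rank")
  for (col in setdiff(cols, names(results))) results[[col]] <- NA
  if ("p_source" %in% names(results)) cols <- c(cols, "p_source")
  results <- rank_results(results)
  utils::write.table(results[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Order per target by descending score, ties by name; assign rank 1..k.
rank_results <- function(results) {
  if (nrow(results) == 0L) { results$rank <- integer(); return(results) }
  pieces <- lapply(split(results, results$target), function(d) {
    d <- d[order(-d$score, d$region_set), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, pieces[unique(results$target)])
  rownames(out) <- NULL
  out
}
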