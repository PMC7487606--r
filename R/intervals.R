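#' Validate a table of genomic intervals
#'
#' Intervals are represented throughout the package as plain data frames with
#' columns `chrom` (character), `start` and `end` (integers, 0-based
#' half-open, BED convention). `start >= 0`, `end > start` and a nonempty
#' chromosome name are enforced.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return The validated data.frame (coordinates coerced to integer-valued
#'   doubles, row names dropped).
#' @export
validate_regions <- function(regions, what = "regions") {
  regions <- as.data.frame(regions)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions))) {
    stop(what, " must have columns chrom, start, end")
  }
  regions <- regions[need]
  regions$chrom <- as.character(regions$chrom)
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  rownames(regions) <- NULL
  if (nrow(regions) == 0L) return(regions)
  if (anyNA(regions$chrom) || any(!nzchar(regions$chrom))) {
    stop(what, ": chromosome names must be nonempty")
  }
  if (anyNA(regions$start) || anyNA(regions$end) ||
      any(regions$start != floor(regions$start)) ||
      any(regions$end != floor(regions$end))) {
    stop(what, ": start/end must be integers")
  }
  if (any(regions$start < 0)) stop(what, ": start must be >= 0")
  if (any(regions$end <= regions$start)) {
    bad <- which(regions$end <= regions$start)[1L]
    stop(what, ": end must exceed start (first offending row ", bad, ")")
  }
  regions
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Find overlapping interval pairs
#'
#' Returns every (query, subject) pair on the same chromosome with
#' `max(starts) < min(ends)` under 0-based half-open coordinates. Abutting
#' intervals do not overlap. Strand is ignored everywhere in this package.
#'
#' @param query,subject interval data.frames (see [validate_regions()]).
#' @return data.frame with columns `query`, `subject` (1-based row indices)
#'   and `width` (overlap length in bases), ordered by query then subject.
#' @examples
#' find_overlaps(data.frame(chrom = "chr1", start = 10, end = 20),
#'               data.frame(chrom = "chr1", start = 15, end = 25))
#' @export
find_overlaps <- function(query, subject) {
  query <- validate_regions(query, "query")
  subject <- validate_regions(subject, "subject")
  empty <- data.frame(query = integer(), subject = integer(),
                      width = numeric())
  if (nrow(query) == 0L || nrow(subject) == 0L) return(empty)
  if (!any(unique(query$chrom) %in% subject$chrom)) {
    # exact-name matching is deliberate; a silent "chr1" vs "1" mismatch
    # would look like absence of overlap, so disjoint name sets are loud
    warning("query and subject share no chromosome names")
    return(empty)
  }
  hits <- GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  w <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  ord <- order(qi, si)
  data.frame(query = qi[ord], subject = si[ord], width = w[ord])
}

#' Merge overlapping intervals
#'
#' Takes the union of a collection of intervals, merging only intervals that
#' genuinely overlap: half-open abutting intervals (chr1:0-10, chr1:10-20)
#' stay separate. Total covered bases are preserved. Output is sorted by
#' (chrom, start).
#'
#' @param regions interval data.frame.
#' @return merged interval data.frame.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(0, 5), end = c(10, 15)))
#' @export
merge_intervals <- function(regions) {
  regions <- validate_regions(regions)
  if (nrow(regions) == 0L) return(regions)
  merged <- GenomicRanges::reduce(as_granges(regions), min.gapwidth = 0L)
  out <- granges_to_df(merged)
  out[order(out$chrom, out$start), , drop = FALSE] |>
    (\(x) { rownames(x) <- NULL; x })()
}

#' Construct a region set
#'
#' A named, ordered collection of genomic intervals sharing a functional
#' annotation (for example ChIP-seq binding sites of one transcription
#' factor). Member regions may overlap each other; no implicit merging.
#'
#' @param name identifier.
#' @param regions interval data.frame.
#' @param metadata named list of free-form annotations (source, factor, ...).
#' @return object of class `region_set`.
#' @export
region_set <- function(name, regions, metadata = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name, regions = validate_regions(regions, name),
         metadata = metadata),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", x$name, "-", nrow(x$regions), "regions\n")
  invisible(x)
}

#' Construct a region set database
#'
#' @param sets list of [region_set()] objects with unique names.
#' @param genome assembly label, informational only.
#' @return object of class `region_set_db`; sets are accessible by name.
#' @export
region_set_db <- function(sets, genome = NA_character_) {
  stopifnot(is.list(sets), length(sets) > 0L)
  ok <- vapply(sets, inherits, logical(1L), what = "region_set")
  if (!all(ok)) stop("all elements must be region_set objects")
  nms <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("region set names must be unique")
  names(sets) <- nms
  structure(list(sets = sets, genome = genome), class = "region_set_db")
}

#' @export
print.region_set_db <- function(x, ...) {
  cat("<region_set_db>", length(x$sets), "region sets")
  if (!is.na(x$genome)) cat(" (", x$genome, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.region_set_db <- function(x) length(x$sets)
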