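# Annotation tracks (conserved TFBS loci, alternative-splicing events,
# promoters, CpG islands) as sorted interval sets, with overlap operations
# backed by GenomicRanges.

TRACK_KINDS <- c("conserved_tfbs", "alt_splicing", "promoter", "cpg_island")

#' Read a BED3/BED4 annotation track
#'
#' Tab-separated, 0-based half-open intervals; an optional fourth column is
#' kept as the interval label (TF name or event type). Intervals are sorted
#' per chromosome after loading.
#'
#' @param path BED file path.
#' @param kind One of `"conserved_tfbs"`, `"alt_splicing"`, `"promoter"`,
#'   `"cpg_island"`.
#' @return A `data.frame` of class `annotation_track` with columns `chrom`,
#'   `start`, `end`, `label` and attribute `kind`.
#' @export
read_bed_track <- function(path, kind = TRACK_KINDS) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .stopf("track file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    tr <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), label = character(0),
                     stringsAsFactors = FALSE)
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    tr <- data.frame(
      chrom = vapply(f, `[`, character(1), 1),
      start = as.integer(vapply(f, `[`, character(1), 2)),
      end = as.integer(vapply(f, `[`, character(1), 3)),
      label = vapply(f, function(x) if (length(x) >= 4) x[4] else ".", character(1)),
      stringsAsFactors = FALSE)
  }
  annotation_track(tr, kind)
}

#' Construct an annotation track from an interval table
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `label` (0-based half-open).
#' @param kind Track kind (see [read_bed_track()]).
#' @return An `annotation_track`, sorted per chromosome.
#' @export
annotation_track <- function(intervals, kind = TRACK_KINDS) {
  kind <- match.arg(kind)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    .stopf("annotation_track: start must be < end (0-based half-open)")
  if (is.null(intervals$label)) intervals$label <- rep(".", nrow(intervals))
  tr <- intervals[order(intervals$chrom, intervals$start, intervals$end),
                  c("chrom", "start", "end", "label"), drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "kind") <- kind
  class(tr) <- c("annotation_track", "data.frame")
  tr
}

# 0-based half-open table -> GRanges (1-based closed internally).
.track_granges <- function(tr) {
  GenomicRanges::GRanges(tr$chrom,
                         IRanges::IRanges(start = tr$start + 1L, end = tr$end))
}

#' Restrict DMS to sites inside a region track
#'
#' Keeps sites whose cytosine position (the single base `start`) overlaps
#' any interval of a promoter or CpG-island track.
#'
#' @param sites A DMS table.
#' @param track An `annotation_track` of kind `promoter` or `cpg_island`.
#' @return The overlapping subset of `sites` (input order preserved).
#' @export
restrict_to_regions <- function(sites, track) {
  kind <- attr(track, "kind")
  if (!kind %in% c("promoter", "cpg_island"))
    .stopf("restrict_to_regions: track kind must be promoter or cpg_island, got %s", kind)
  if (!nrow(track) || !nrow(sites)) return(sites[integer(0), , drop = FALSE])
  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(start = sites$start + 1L, width = 1L))
  hit <- IRanges::overlapsAny(q, .track_granges(track))
  sites[hit, , drop = FALSE]
}

#' Count track intervals intersecting a window
#'
#' The number of intervals of `track` that intersect
#' `[window_start, window_end)` on the window's chromosome; feeds the
#' signature attributes `cTFBS` and the alternative-splicing occurrence.
#'
#' @param window A `seq_window`, or a `data.frame` of windows from
#'   [fetch_windows()] (then a vector is returned).
#' @param track An `annotation_track`.
#' @return Non-negative integer (vector).
#' @export
count_track_overlaps <- function(window, track) {
  if (inherits(window, "seq_window"))
    window <- data.frame(chrom = window$chrom,
                         window_start = window$window_start,
                         window_end = window$window_end,
                         stringsAsFactors = FALSE)
  if (!nrow(track)) return(integer(nrow(window)))
  q <- GenomicRanges::GRanges(window$chrom,
                              IRanges::IRanges(start = window$window_start + 1L,
                                               end = window$window_end))
  GenomicRanges::countOverlaps(q, .track_granges(track))
}
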