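# Pentamer-table DNA shape: predicted local helix geometry (minor groove
# width MGW, Roll, propeller twist ProT, helix twist HelT) for the native
# window versus the window with its central CpG methylated, decoded from a
# 5-mer lookup table. Methylation is encoded symmetrically over the CpG
# dyad: C -> M (5-methylcytosine) and the G paired to it on the opposite
# strand -> W. Real pentamer tables are loadable from TSV; a seeded
# synthetic table generator is provided for download-free testing.

SHAPE_NAMES <- c("MGW", "Roll", "ProT", "HelT")
.shape_alphabet <- c("A", "C", "G", "T", "M", "W")

#' Read a pentamer shape table from TSV
#'
#' Expected columns: `pentamer` (5-mers over A,C,G,T,M,W) and one numeric
#' column per shape (`MGW`, `Roll`, `ProT`, `HelT`); header required.
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `shape_table`.
#' @export
read_shape_table <- function(path) {
  if (!file.exists(path)) .stopf("shape table not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"pentamer" %in% names(tab))
    .stopf("shape table needs a 'pentamer' column")
  missing <- setdiff(SHAPE_NAMES, names(tab))
  if (length(missing))
    .stopf("shape table missing shape column(s): %s", paste(missing, collapse = ", "))
  if (any(nchar(tab$pentamer) != 5L))
    .stopf("shape table: all pentamers must have length 5")
  class(tab) <- c("shape_table", "data.frame")
  tab
}

#' Generate a synthetic pentamer shape table
#'
#' Covers every 5-mer over the extended alphabet A,C,G,T,M,W with values
#' drawn uniformly from shape-typical ranges (MGW in Angstrom around
#' 4.0-6.2, Roll in degrees -8..8, ProT -18..-5, HelT 30..40).
#' Deterministic under `seed`. This synthetic table preserves the interface
#' and statistics of real pentamer tables but carries no structural
#' information; substitute a real table for biological inference.
#'
#' @param seed Integer seed.
#' @return A `shape_table` covering all 6^5 pentamers.
#' @export
synthetic_shape_table <- function(seed = 1L) {
  pent <- do.call(paste0, expand.grid(rep(list(.shape_alphabet), 5),
                                      stringsAsFactors = FALSE)[, 5:1])
  n <- length(pent)
  tab <- withr_seed(seed, data.frame(
    pentamer = pent,
    MGW = stats::runif(n, 4.0, 6.2),
    Roll = stats::runif(n, -8, 8),
    ProT = stats::runif(n, -18, -5),
    HelT = stats::runif(n, 30, 40),
    stringsAsFactors = FALSE
  ))
  class(tab) <- c("shape_table", "data.frame")
  tab
}

# Named lookup vector for one shape.
.shape_lookup <- function(table, shape_name) {
  v <- table[[shape_name]]
  names(v) <- table$pentamer
  v
}

#' Methylation-induced DNA shape change at the central CpG
#'
#' Decodes two per-position shape profiles over the window - one from the
#' native sequence and one with the central CpG encoded as methylated
#' (C to M and the opposite-strand G to W) - and returns their difference
#' (methylated minus unmethylated). Positions are scorable when a full
#' pentamer centers on them (positions 3..L-2, 1-based). The p-value is a
#' two-sided Wilcoxon signed-rank test over the informative positions (those
#' whose pentamer covers a modified base); with fewer than 4 informative
#' positions, or all-zero differences, the test is degenerate and p = 1.
#'
#' @param window A `seq_window` (see [fetch_window()]); the site position
#'   must hold a CpG (C at `center`, G at `center + 1`).
#' @param table A `shape_table`.
#' @param shape_name One of `"MGW"`, `"Roll"`, `"ProT"`, `"HelT"`.
#' @param default Value used for pentamers absent from the table; if NULL
#'   (default) a missing pentamer is an error naming it.
#' @return A list of class `shape_delta` with `shape`, `positions` (1-based
#'   window positions), `native`, `methylated`, `delta`, `informative`
#'   (logical), `p_value`.
#' @export
shape_delta <- function(window, table, shape_name, default = NULL) {
  stopifnot(inherits(window, "seq_window"))
  shape_name <- match.arg(shape_name, SHAPE_NAMES)
  seq <- window$seq
  L <- nchar(seq)
  if (L < 5L) .stopf("shape_delta: window length must be >= 5")
  c1 <- window$center + 1L  # 1-based position of the cytosine
  if (substr(seq, c1, c1) != "C" || c1 + 1L > L || substr(seq, c1 + 1L, c1 + 1L) != "G")
    .stopf("shape_delta: no CpG at the site position (window %s:%d)",
           window$chrom, window$window_start + window$center)
  mseq <- seq
  substr(mseq, c1, c1) <- "M"
  substr(mseq, c1 + 1L, c1 + 1L) <- "W"
  pos <- 3:(L - 2L)
  pent_n <- substring(seq, pos - 2L, pos + 2L)
  pent_m <- substring(mseq, pos - 2L, pos + 2L)
  lut <- .shape_lookup(table, shape_name)
  decode <- function(p) {
    v <- lut[p]
    if (anyNA(v)) {
      miss <- unique(p[is.na(v)])
      if (is.null(default))
        .stopf("shape_delta: pentamer(s) absent from table: %s",
               paste(utils::head(miss, 5), collapse = ", "))
      v[is.na(v)] <- default
    }
    unname(v)
  }
  native <- decode(pent_n)
  meth <- decode(pent_m)
  delta <- meth - native
  informative <- pos >= c1 - 2L & pos <= c1 + 3L
  d <- delta[informative]
  d <- d[!is.na(d)]
  if (length(d) < 4L || all(d == 0)) {
    p <- 1
  } else {
    p <- suppressWarnings(stats::wilcox.test(d, mu = 0)$p.value)
    if (is.na(p)) p <- 1
  }
  structure(list(shape = shape_name, positions = pos, native = native,
                 methylated = meth, delta = delta, informative = informative,
                 p_value = p),
            class = "shape_delta")
}

#' Shape changes for all four shapes at one window
#'
#' @inheritParams shape_delta
#' @return Named list of `shape_delta` objects (MGW, Roll, ProT, HelT).
#' @export
shape_deltas_all <- function(window, table, default = NULL) {
  stats::setNames(lapply(SHAPE_NAMES, function(s)
    shape_delta(window, table, s, default = default)), SHAPE_NAMES)
}

#' Joined shape-change logical
#'
#' TRUE iff at least one shape change is significant (minimum p-value below
#' `alpha`). An empty list returns FALSE with a warning.
#'
#' @param deltas List of `shape_delta` objects.
#' @param alpha Significance level, default 0.05.
#' @return Logical scalar.
#' @export
shape_significant <- function(deltas, alpha = 0.05) {
  if (!length(deltas)) {
    .warnf("shape_significant: empty shape list, returning FALSE")
    return(FALSE)
  }
  p <- vapply(deltas, function(d) d$p_value, numeric(1))
  min(p) < alpha
}
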