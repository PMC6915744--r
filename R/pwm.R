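# JASPAR-style position frequency matrices, log-odds PWMs and window
# scanning with min-max relative scores.

#' Load position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR PFM text format: a `>` header line with motif id and
#' name, followed by four labeled base rows of bracketed counts, e.g.
#' `A [ 0 3 79 ... ]`. Row order is normalized to A, C, G, T regardless of
#' the order in the file. A matrix with a zero-sum column, fewer than 4
#' columns, or a missing base row is rejected with an error naming the
#' motif.
#'
#' @param path Path to the JASPAR-format text file.
#' @return List of PFMs; each a list with `motif_id`, `motif_name`,
#'   `counts` (4 x L numeric matrix, rownames A,C,G,T).
#' @export
load_jaspar_pfms <- function(path) {
  if (!file.exists(path)) .stopf("PFM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) .stopf("no JASPAR records in %s", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    motif_id <- toks[1]
    motif_name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else motif_id
    body <- lines[(heads[k] + 1L):(bounds[k + 1L] - 1L)]
    rows <- list()
    for (ln in body) {
      m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\s*\\[?([^]]*)\\]?\\s*$", ln,
                                  perl = TRUE))[[1]]
      if (length(m) < 3L) .stopf("malformed matrix row in motif %s: '%s'", motif_id, ln)
      base <- toupper(m[2])
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      if (anyNA(vals)) .stopf("non-numeric counts in motif %s row %s", motif_id, base)
      rows[[base]] <- vals
    }
    if (!all(c("A", "C", "G", "T") %in% names(rows)))
      .stopf("motif %s: missing base row(s) %s", motif_id,
             paste(setdiff(c("A", "C", "G", "T"), names(rows)), collapse = ", "))
    L <- unique(lengths(rows))
    if (length(L) != 1L) .stopf("motif %s: rows of unequal length", motif_id)
    if (L < 4L) .stopf("motif %s: length %d < 4", motif_id, L)
    counts <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    if (any(counts < 0)) .stopf("motif %s: negative counts", motif_id)
    if (any(colSums(counts) <= 0)) .stopf("motif %s: column with no positive count", motif_id)
    out[[k]] <- list(motif_id = motif_id, motif_name = motif_name, counts = counts)
  }
  names(out) <- vapply(out, `[[`, character(1), "motif_id")
  out
}

#' Convert a position frequency matrix to a log-odds PWM
#'
#' Per-cell probability \eqn{p_b = (n_b + pc \cdot bg_b) / (N + pc)} where
#' `N` is the column total and the pseudocount `pc` is allocated across
#' bases proportionally to the background; the PWM cell is
#' \eqn{\log_2(p_b / bg_b)}. The maximum and minimum achievable scores (sums
#' of column maxima/minima) are recorded for relative scoring.
#'
#' @param pfm A PFM as returned by [load_jaspar_pfms()] (or a bare 4 x L
#'   counts matrix with rownames A,C,G,T).
#' @param pseudocount Total pseudocount per column, default 0.8.
#' @param background Base composition (A,C,G,T) summing to 1; default
#'   uniform.
#' @return A list of class `pwm` with `motif_id`, `matrix` (4 x L log-odds),
#'   `min_score`, `max_score`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8, background = rep(0.25, 4)) {
  counts <- if (is.list(pfm)) pfm$counts else pfm
  motif_id <- if (is.list(pfm)) pfm$motif_id else "pwm"
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (any(background <= 0)) .stopf("pfm_to_pwm: background entries must be positive")
  if (abs(sum(background) - 1) > 1e-8) .stopf("pfm_to_pwm: background must sum to 1")
  N <- colSums(counts)
  prob <- sweep(counts + pseudocount * background,
                2, N + pseudocount, "/")
  m <- log2(prob / background)
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = m,
                 min_score = sum(apply(m, 2, min)),
                 max_score = sum(apply(m, 2, max))),
            class = "pwm")
}

# Score every placement of a 4 x L score matrix along an encoded sequence.
# Placements covering N (NA codes) score NA.
.scan_scores <- function(codes, m) {
  L <- ncol(m)
  n <- length(codes)
  if (n < L) return(numeric(0))
  nplace <- n - L + 1L
  idx <- matrix(0L, nrow = nplace, ncol = L)
  for (j in seq_len(L)) idx[, j] <- codes[j:(nplace + j - 1L)]
  vals <- matrix(m[cbind(as.vector(idx), rep(seq_len(L), each = nplace))],
                 nrow = nplace)
  rowSums(vals)
}

#' Scan a window for PWM hits above a relative-score threshold
#'
#' Every offset and strand with relative score
#' \eqn{(s - s_{min}) / (s_{max} - s_{min}) \ge} `min_rel_score` is
#' reported. Placements containing N are skipped, never scored.
#'
#' @param window A `seq_window` or DNA string.
#' @param pwm A `pwm` from [pfm_to_pwm()].
#' @param min_rel_score Relative score threshold in \eqn{[0, 1]}, default 0.8.
#' @param both_strands Scan the minus strand too, default TRUE.
#' @return `data.frame` with columns `motif_id`, `start` (0-based,
#'   window-relative), `strand`, `score`, `rel_score`.
#' @export
scan_pwm <- function(window, pwm, min_rel_score = 0.8, both_strands = TRUE) {
  if (min_rel_score < 0 || min_rel_score > 1)
    .stopf("scan_pwm: min_rel_score must lie in [0, 1]")
  stopifnot(inherits(pwm, "pwm"))
  seq <- if (inherits(window, "seq_window")) window$seq else window
  L <- ncol(pwm$matrix)
  if (nchar(seq) < L)
    .stopf("scan_pwm: window shorter than motif (%d < %d)", nchar(seq), L)
  rng <- pwm$max_score - pwm$min_score
  one_strand <- function(s, strand) {
    codes <- .encode_dna(s)
    sc <- .scan_scores(codes, pwm$matrix)
    rel <- (sc - pwm$min_score) / rng
    hit <- which(!is.na(rel) & rel >= min_rel_score)
    if (!length(hit)) return(NULL)
    start0 <- if (strand == "+") hit - 1L else nchar(s) - (hit - 1L) - L
    data.frame(motif_id = pwm$motif_id, start = start0, strand = strand,
               score = sc[hit], rel_score = rel[hit], stringsAsFactors = FALSE)
  }
  rows <- list(one_strand(seq, "+"))
  if (both_strands) rows <- c(rows, list(one_strand(revcomp(seq), "-")))
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(motif_id = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Total PWM hit count over a motif set
#'
#' Per-window TFBS count: the number of [scan_pwm()] hits summed over the
#' supplied motifs. Feeds the signature attribute `TFBS`.
#'
#' @param window A `seq_window` or DNA string.
#' @param pwms List of `pwm` objects.
#' @inheritParams scan_pwm
#' @return Non-negative integer.
#' @export
tfbs_count <- function(window, pwms, min_rel_score = 0.8, both_strands = TRUE) {
  sum(vapply(pwms, function(p)
    nrow(scan_pwm(window, p, min_rel_score, both_strands)), integer(1)))
}

#' Consensus sequence of a PFM
#'
#' Per-column argmax base; ties resolved in A,C,G,T order for determinism.
#'
#' @param pfm A PFM (list with `counts`) or bare 4 x L matrix.
#' @return Character string of length L.
#' @export
pfm_consensus <- function(pfm) {
  counts <- if (is.list(pfm)) pfm$counts else pfm
  paste(c("A", "C", "G", "T")[apply(counts, 2, which.max)], collapse = "")
}
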