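# Canonical G-quadruplex motif detection.
#
# A canonical quadruplex-forming sequence is four runs of >= min_run
# guanines separated by three loops whose lengths lie in
# [loop_min, loop_max]. Loops may contain any of A, C, G, T; N breaks a
# match. Overlapping candidates are resolved greedily left-to-right, taking
# the longest match at each start, which makes counts stable and
# order-independent.

# One-strand scan. Returns matches as 1-based [s, e] inclusive plus a
# traceback of the chosen run/loop decomposition.
.g4_scan_strand <- function(chars, min_run, loop_min, loop_max) {
  n <- length(chars)
  minlen <- 4L * min_run + 3L * loop_min
  if (n < minlen) return(list())
  isG <- chars == "G"
  ok_loop_char <- chars %in% c("A", "C", "G", "T")
  # gl[i]: length of the G-run starting at i (0 if chars[i] != "G")
  gl <- integer(n)
  for (i in n:1) gl[i] <- if (isG[i]) (if (i < n) gl[i + 1L] else 0L) + 1L else 0L
  # cumulative count of loop-legal chars for O(1) "no N in loop" checks
  cs <- cumsum(ok_loop_char)
  loop_clean <- function(a, b) {            # positions a..b all loop-legal
    if (a > b) return(TRUE)
    (cs[b] - if (a > 1L) cs[a - 1L] else 0L) == (b - a + 1L)
  }
  # best[pos, k]: furthest 1-based end of a valid tail of k runs starting
  # with a G-run at pos; NA if none. Filled right-to-left.
  best <- matrix(NA_integer_, nrow = n, ncol = 4L)
  choice <- matrix(NA_integer_, nrow = n, ncol = 4L) # run_len*100 + loop_len
  for (pos in n:1) {
    if (gl[pos] < min_run) next
    best[pos, 1L] <- pos + gl[pos] - 1L
    choice[pos, 1L] <- gl[pos] * 100L
    for (k in 2:4) {
      b <- NA_integer_; ch <- NA_integer_
      for (run_len in min_run:gl[pos]) {
        for (loop_len in loop_min:loop_max) {
          nxt <- pos + run_len + loop_len
          if (nxt > n) next
          if (!loop_clean(pos + run_len, nxt - 1L)) next
          e <- best[nxt, k - 1L]
          if (!is.na(e) && (is.na(b) || e > b)) {
            b <- e; ch <- run_len * 100L + loop_len
          }
        }
      }
      best[pos, k] <- b; choice[pos, k] <- ch
    }
  }
  # Greedy left-to-right selection of non-overlapping matches.
  out <- list(); s <- 1L
  while (s <= n - minlen + 1L) {
    e <- best[s, 4L]
    if (!is.na(e)) {
      # Traceback for the run/loop decomposition achieving end e.
      loops <- integer(0); pos <- s
      for (k in 4:2) {
        ch <- choice[pos, k]
        run_len <- ch %/% 100L; loop_len <- ch %% 100L
        loops <- c(loops, loop_len)
        pos <- pos + run_len + loop_len
      }
      out[[length(out) + 1L]] <- list(s = s, e = e, loops = loops)
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  out
}

#' Find canonical G-quadruplex motifs
#'
#' Detects all maximal non-overlapping canonical quadruplex matches: four
#' runs of at least `min_run` G separated by loops with lengths in
#' `[loop_min, loop_max]`. Minus-strand quadruplexes (C-run pattern on the
#' input, equivalently the G pattern on the reverse complement) are included
#' when `both_strands` is TRUE; greedy resolution is applied per strand.
#'
#' @param sequence Nonempty DNA string (A/C/G/T/N; case-insensitive).
#' @param min_run Minimum G-run length, default 3.
#' @param loop_min,loop_max Loop length bounds, defaults 1 and 7.
#' @param both_strands Also scan the minus strand, default TRUE.
#' @return `data.frame` with columns `start`, `end` (0-based half-open,
#'   relative to `sequence`), `strand`, `n_runs`, `loop_lengths`
#'   (comma-separated, in match orientation).
#' @export
find_g4 <- function(sequence, min_run = 3L, loop_min = 1L, loop_max = 7L,
                    both_strands = TRUE) {
  if (!nzchar(sequence)) .stopf("find_g4: sequence must be nonempty")
  if (loop_min > loop_max) .stopf("find_g4: loop_min > loop_max")
  if (min_run < 2L) .stopf("find_g4: min_run must be >= 2")
  chars <- .split1(toupper(sequence))
  n <- length(chars)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), n_runs = integer(0),
                      loop_lengths = character(0), stringsAsFactors = FALSE)
  rows <- list()
  plus <- .g4_scan_strand(chars, min_run, loop_min, loop_max)
  for (m in plus)
    rows[[length(rows) + 1L]] <- data.frame(
      start = m$s - 1L, end = m$e, strand = "+", n_runs = 4L,
      loop_lengths = paste(m$loops, collapse = ","), stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- .split1(revcomp(paste(chars, collapse = "")))
    minus <- .g4_scan_strand(rc, min_run, loop_min, loop_max)
    for (m in minus)
      rows[[length(rows) + 1L]] <- data.frame(
        start = n - m$e, end = n - m$s + 1L, strand = "-", n_runs = 4L,
        loop_lengths = paste(m$loops, collapse = ","), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' G-quadruplex count in a sequence window
#'
#' Number of matches reported by [find_g4()]; feeds the signature attribute
#' `G4`.
#'
#' @param window A `seq_window` (see [fetch_window()]) or a DNA string.
#' @inheritParams find_g4
#' @return Non-negative integer.
#' @export
g4_count <- function(window, min_run = 3L, loop_min = 1L, loop_max = 7L,
                     both_strands = TRUE) {
  s <- if (inherits(window, "seq_window")) window$seq else window
  nrow(find_g4(s, min_run, loop_min, loop_max, both_strands))
}
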