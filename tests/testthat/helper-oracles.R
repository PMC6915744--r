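# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle recomputes its quantity from the definition by a
# different algorithm than the package implementation.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Plain-character reverse complement for oracle-internal use.
.orc_revcomp <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  cc <- c(A = "T", C = "G", G = "C", T = "A")[ch]
  cc[is.na(cc)] <- "X"   # N and anything else can never pair
  paste(rev(cc), collapse = "")
}

# --- G-quadruplex: exhaustive anchored-regex enumerator ------------------
# A match exists at (s, e) iff substring s..e fully matches
# G{r,}([ACGT]{lmin,lmax}G{r,}){3}. Greedy left-to-right selection taking
# the longest match at each start, as the detector's documented policy.
oracle_g4_strand <- function(s, min_run, loop_min, loop_max) {
  n <- nchar(s)
  minlen <- 4 * min_run + 3 * loop_min
  pat <- sprintf("^G{%d,}([ACGT]{%d,%d}G{%d,}){3}$",
                 min_run, loop_min, loop_max, min_run)
  best <- rep(NA_integer_, n)
  for (st in seq_len(n)) {
    if (substr(s, st, st) != "G") next
    maxlen <- n - st + 1L
    if (maxlen < minlen) next
    lens <- minlen:maxlen
    subs <- substring(s, st, st + lens - 1L)
    ok <- grepl(pat, subs, perl = TRUE)
    if (any(ok)) best[st] <- st + max(lens[ok]) - 1L
  }
  res <- NULL; st <- 1L
  while (st <= n) {
    if (!is.na(best[st])) {
      res <- rbind(res, c(st, best[st]))
      st <- best[st] + 1L
    } else st <- st + 1L
  }
  res
}

oracle_g4 <- function(seq, min_run = 3, loop_min = 1, loop_max = 7,
                      both_strands = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- NULL
  p <- oracle_g4_strand(seq, min_run, loop_min, loop_max)
  if (!is.null(p))
    out <- data.frame(start = p[, 1] - 1L, end = p[, 2], strand = "+")
  if (both_strands) {
    m <- oracle_g4_strand(.orc_revcomp(seq), min_run, loop_min, loop_max)
    if (!is.null(m))
      out <- rbind(out, data.frame(start = n - m[, 2], end = n - m[, 1] + 1L,
                                   strand = "-"))
  }
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0), strand = character(0))
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- Palindromes: brute-force (center, loop) enumeration -----------------
# For each inner boundary i (1-based position after the left arm) and loop
# length l, grow the arm by whole-substring reverse-complement comparison;
# report the maximal arm, suppressing inward-extendable matches.
oracle_palindromes <- function(seq, min_arm = 6, max_loop = 10) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- NULL
  for (i in 2:n) {
    for (l in 0:max_loop) {
      if (i + l > n + 1L) next
      amax <- 0L
      a <- 1L
      while (i - a >= 1L && i + l + a - 1L <= n) {
        left <- substr(seq, i - a, i - 1L)
        right <- substr(seq, i + l, i + l + a - 1L)
        if (grepl("[^ACGT]", left) || grepl("[^ACGT]", right)) break
        if (left != .orc_revcomp(right)) break
        amax <- a
        a <- a + 1L
      }
      if (amax < min_arm) next
      if (l >= 2L) {
        il <- substr(seq, i, i)
        ir <- substr(seq, i + l - 1L, i + l - 1L)
        if (il %in% c("A", "C", "G", "T") && il == .orc_revcomp(ir)) next
      }
      out <- rbind(out, data.frame(arm_start = i - amax - 1L,
                                   arm_length = amax, loop_length = l))
    }
  }
  if (is.null(out))
    out <- data.frame(arm_start = integer(0), arm_length = integer(0),
                      loop_length = integer(0))
  out[order(out$arm_start, out$loop_length), , drop = FALSE]
}

# --- PWM scan: naive per-offset rescoring --------------------------------
oracle_scan_pwm <- function(seq, pwm, min_rel_score = 0.8, both_strands = TRUE) {
  seq <- toupper(seq)
  L <- ncol(pwm$matrix)
  n <- nchar(seq)
  score_at <- function(s, off) {
    tot <- 0
    for (j in seq_len(L)) {
      b <- substr(s, off + j - 1L, off + j - 1L)
      if (!b %in% c("A", "C", "G", "T")) return(NA_real_)
      tot <- tot + pwm$matrix[b, j]
    }
    tot
  }
  rows <- NULL
  for (strand in if (both_strands) c("+", "-") else "+") {
    s <- if (strand == "+") seq else .orc_revcomp(seq)
    for (off in seq_len(n - L + 1L)) {
      sc <- score_at(s, off)
      if (is.na(sc)) next
      rel <- (sc - pwm$min_score) / (pwm$max_score - pwm$min_score)
      if (rel >= min_rel_score) {
        start0 <- if (strand == "+") off - 1L else n - (off - 1L) - L
        rows <- rbind(rows, data.frame(start = start0, strand = strand,
                                       score = sc, rel_score = rel,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows))
    rows <- data.frame(start = integer(0), strand = character(0),
                       score = numeric(0), rel_score = numeric(0))
  rows[order(rows$start, rows$strand), , drop = FALSE]
}

# --- Splice sites: naive per-offset percentile rescoring -----------------
oracle_splice_hits <- function(seq, model, min_score = 80, both_strands = TRUE) {
  seq <- toupper(seq)
  L <- model$length
  n <- nchar(seq)
  tmin <- sum(apply(model$freq, 2, min))
  tmax <- sum(apply(model$freq, 2, max))
  rows <- NULL
  for (strand in if (both_strands) c("+", "-") else "+") {
    s <- if (strand == "+") seq else .orc_revcomp(seq)
    for (off in seq_len(n - L + 1L)) {
      kmer <- substr(s, off, off + L - 1L)
      if (grepl("[^ACGT]", kmer)) next
      ch <- strsplit(kmer, "", fixed = TRUE)[[1]]
      t <- sum(vapply(seq_len(L), function(j) model$freq[ch[j], j], numeric(1)))
      sc <- 100 * (t - tmin) / (tmax - tmin)
      if (sc >= min_score) {
        start0 <- if (strand == "+") off - 1L else n - (off - 1L) - L
        rows <- rbind(rows, data.frame(start = start0, strand = strand,
                                       score = sc, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows))
    rows <- data.frame(start = integer(0), strand = character(0), score = numeric(0))
  rows[order(rows$start, rows$strand), , drop = FALSE]
}

# --- Interval overlap: quadratic all-pairs count -------------------------
oracle_overlap_counts <- function(windows, track) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(track$chrom == windows$chrom[i] &
          track$start < windows$window_end[i] &
          track$end > windows$window_start[i])
  }, numeric(1))
}

# --- Benjamini-Hochberg: textbook step-up --------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# --- Small fixture builders ----------------------------------------------
fixture_pwms <- function() {
  path <- system.file("extdata", "motifs_synthetic.jaspar", package = "methsig")
  lapply(load_jaspar_pfms(path), pfm_to_pwm)
}

fixture_donor <- function() default_donor_model()
fixture_acceptor <- function() default_acceptor_model()

# Identity-valued shape table: M/W pentamers share the value of their
# unmethylated counterparts; optional uniform shift applied to every
# pentamer containing M or W.
fixture_shape_table <- function(shift = 0, seed = 42) {
  tab <- synthetic_shape_table(seed)
  base_idx <- match(chartr("MW", "CG", tab$pentamer), tab$pentamer)
  mod <- grepl("[MW]", tab$pentamer)
  for (s in c("MGW", "Roll", "ProT", "HelT")) {
    tab[[s]] <- tab[[s]][base_idx]
    tab[[s]][mod] <- tab[[s]][mod] + shift
  }
  tab
}

# A tiny in-memory window around position `center` of `seq`.
as_window <- function(seq, center, chrom = "chrT", window_start = 0L) {
  structure(list(chrom = chrom, window_start = window_start,
                 window_end = window_start + nchar(seq), center = center,
                 clipped = FALSE, seq = seq),
            class = "seq_window")
}
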