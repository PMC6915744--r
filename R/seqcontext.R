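# Fixed-offset sequence windows around DMS and compositional statistics.

#' Read a reference genome FASTA
#'
#' Sequence names are truncated at the first whitespace, matching common
#' chromosome naming. Soft-masked (lowercase) bases are uppercased and used
#' by default; `mask_soft = TRUE` converts them to N instead. The masking
#' policy must be applied here because DNA string containers store bases
#' case-insensitively.
#'
#' @param path FASTA file path.
#' @param mask_soft Treat soft-masked bases as N, default FALSE.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path, mask_soft = FALSE) {
  if (!file.exists(path)) .stopf("genome FASTA not found: %s", path)
  if (mask_soft) {
    lines <- readLines(path, warn = FALSE)
    seq_lines <- !grepl("^>", lines)
    lines[seq_lines] <- gsub("[a-z]", "N", lines[seq_lines])
    tmp <- tempfile(fileext = ".fa")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    path <- tmp
  }
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a sequence window centered at a DMS
#'
#' The window is \eqn{[start - offset, start + offset)} in 0-based half-open
#' coordinates (2 x offset bases total; the default offset of 50 yields a
#' 100 nt window), clipped at the chromosome bounds with the clipping
#' recorded. The soft-masking policy (uppercase vs N) is chosen at genome
#' load time, see [read_genome()].
#'
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param chrom Chromosome name (must be present in `genome`).
#' @param pos 0-based position of the CpG cytosine.
#' @param offset Bases on each side of the cytosine, default 50.
#' @return A list of class `seq_window` with elements `chrom`,
#'   `window_start`, `window_end`, `center` (0-based position of the site
#'   within the window), `clipped`, `seq` (uppercase character string).
#' @export
fetch_window <- function(genome, chrom, pos, offset = 50L) {
  if (!.is_count1(offset)) .stopf("fetch_window: offset must be a positive integer")
  if (!chrom %in% names(genome))
    .stopf("fetch_window: chromosome '%s' not in genome (available: %s)",
           chrom, paste(names(genome), collapse = ", "))
  clen <- Biostrings::width(genome[chrom])
  if (pos < 0 || pos >= clen)
    .stopf("fetch_window: position %d outside chromosome %s [0, %d)", pos, chrom, clen)
  ws <- max(0L, pos - offset)
  we <- min(clen, pos + offset)
  s <- toupper(as.character(Biostrings::subseq(genome[[chrom]], start = ws + 1L,
                                               end = we)))
  structure(list(chrom = chrom, window_start = ws, window_end = we,
                 center = pos - ws, clipped = (we - ws) < 2L * offset,
                 seq = s),
            class = "seq_window")
}

#' Extract windows for every site of a DMS table
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param dms A DMS table with columns `site_id`, `chrom`, `start`.
#' @inheritParams fetch_window
#' @return `data.frame` with columns `site_id`, `chrom`, `window_start`,
#'   `window_end`, `center`, `clipped`, `seq`, rows in `dms` order.
#' @export
fetch_windows <- function(genome, dms, offset = 50L) {
  rows <- lapply(seq_len(nrow(dms)), function(i) {
    w <- fetch_window(genome, dms$chrom[i], dms$start[i], offset)
    data.frame(site_id = dms$site_id[i], chrom = w$chrom,
               window_start = w$window_start, window_end = w$window_end,
               center = w$center, clipped = w$clipped, seq = w$seq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' G+C content of DNA sequences
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from both numerator
#' and denominator. All-N (or empty-after-exclusion) sequences return NA.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector in \eqn{[0, 1]} (NA where undefined).
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) .stopf("gc_content: empty sequence")
  s <- toupper(sequence)
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  ifelse(acgt > 0, gc / acgt, NA_real_)
}

#' Observed/expected CpG ratio
#'
#' Gardiner-Garden & Frommer form: (#CpG x L) / (#C x #G) with L the length
#' excluding N. Returns NA when the sequence has no C or no G.
#'
#' @param sequence Character vector of DNA sequences.
#' @return Non-negative numeric vector (NA where undefined).
#' @export
cpg_oe_ratio <- function(sequence) {
  if (any(!nzchar(sequence))) .stopf("cpg_oe_ratio: empty sequence")
  s <- toupper(sequence)
  nc <- nchar(gsub("[^C]", "", s))
  ng <- nchar(gsub("[^G]", "", s))
  L <- nchar(gsub("[^ACGT]", "", s))
  ncpg <- vapply(gregexpr("CG", s, fixed = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  ifelse(nc > 0 & ng > 0, ncpg * L / (nc * ng), NA_real_)
}

#' Export windows as BED6 and FASTA
#'
#' @param windows Output of [fetch_windows()].
#' @param bed_path,fasta_path Output file paths (either may be NULL).
#' @return Invisibly, the windows table.
#' @export
export_windows <- function(windows, bed_path = NULL, fasta_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(windows$chrom, windows$window_start, windows$window_end,
                      windows$site_id, 0L, "+")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(windows$seq)
    names(ss) <- windows$site_id
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(windows)
}
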