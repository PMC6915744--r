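# Seeded synthetic data: random genomes with CpG target sites, planted
# feature motifs, bimodal beta-value matrices with designated differential
# sites, and coupled expression tables. All generators are pure functions
# of the configuration (identical output under identical seeds), so every
# stage of the framework and the end-to-end ranking are testable with no
# external downloads.

# Fixed planted motifs (documented strings, so detector recall is exactly
# testable at default parameters):
#   g4    -- canonical four-run quadruplex, runs of 3 G, TTA loops
#   pal   -- palindrome with 8 nt arms and a 4 nt loop
#   tfbs  -- consensus of the bundled synthetic motif SYN0001.1
#   donor -- donor-site consensus of the bundled Shapiro-Senapathy table
PLANT_MOTIFS <- c(
  g4 = "GGGTTAGGGTTAGGGTTAGGG",
  pal = "GCCATTGCTTTTGCAATGGC",
  tfbs = "AGCCAGTCTAGC",
  donor = "CAGGTAAGT"
)
# Window-relative 0-based offsets of each motif (window = [site-50, site+50);
# the CpG occupies relative positions 50-51; plants never touch it or each
# other).
PLANT_OFFSETS <- c(g4 = 2L, pal = 26L, tfbs = 54L, donor = 72L)

#' Simulation configuration
#'
#' @param seed Integer seed (mandatory; all generators derive their
#'   randomness from it).
#' @param genome_length Genome length in bases, default 150000.
#' @param gc_fraction Target G+C fraction, default 0.45.
#' @param n_sites Number of CpG target sites, default 400.
#' @param n_enriched Number of "enriched" sites (the rest are "desert"),
#'   default `n_sites / 2`.
#' @param n_samples_per_group Samples per group for beta matrices, default 10.
#' @param beta_modes Shape parameters of the two Beta mixture components
#'   (`low` = unmethylated mode, `high` = methylated mode), defaults
#'   Beta(0.5, 5) and Beta(5, 0.5) for the array-like bimodal shape.
#' @param plant_prob Per-feature planting probability per site class,
#'   defaults `list(enriched = 0.9, desert = 0.05)`.
#' @param effect \eqn{\Delta\beta} magnitude of differential sites, default 0.6.
#' @param offset Window half-width in bases, default 50.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, genome_length = 150000L, gc_fraction = 0.45,
                       n_sites = 400L, n_enriched = NULL,
                       n_samples_per_group = 10L,
                       beta_modes = list(low = c(0.5, 5), high = c(5, 0.5)),
                       plant_prob = list(enriched = 0.9, desert = 0.05),
                       effect = 0.6, offset = 50L) {
  if (missing(seed)) .stopf("sim_config: seed is mandatory")
  if (genome_length < 1000L) .stopf("sim_config: genome_length must be >= 1000")
  if (gc_fraction < 0 || gc_fraction > 1) .stopf("sim_config: gc_fraction in [0, 1]")
  if (n_samples_per_group < 3L) .stopf("sim_config: n_samples_per_group must be >= 3")
  if (is.null(n_enriched)) n_enriched <- n_sites %/% 2L
  stopifnot(n_enriched <= n_sites)
  if (any(unlist(plant_prob) < 0) || any(unlist(plant_prob) > 1))
    .stopf("sim_config: planting probabilities must lie in [0, 1]")
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, n_sites = as.integer(n_sites),
                 n_enriched = as.integer(n_enriched),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 beta_modes = beta_modes, plant_prob = plant_prob,
                 effect = effect, offset = as.integer(offset)),
            class = "sim_config")
}

#' Generate a random genome with spaced CpG target sites
#'
#' Draws a random sequence at the requested G+C fraction, places `n_sites`
#' evenly spaced target sites (windows never overlap), writes a CpG at each
#' site, and assigns site classes ("enriched"/"desert") at random.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a one-chromosome
#'   [Biostrings::DNAStringSet] named `chrS`) and `sites` (`data.frame`:
#'   `site_id`, `chrom`, `start`, `end`, `class`).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  gc <- config$gc_fraction
  margin <- config$offset + 5L
  spacing <- (L - 2L * margin) %/% max(config$n_sites, 1L)
  if (spacing < 2L * config$offset + 10L)
    .stopf("make_genome: genome too short for %d non-overlapping windows",
           config$n_sites)
  withr_seed(config$seed, {
    bases <- sample(c("A", "T", "G", "C"), L, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    cls <- sample(rep(c("enriched", "desert"),
                      c(config$n_enriched, config$n_sites - config$n_enriched)))
    seq <- paste(bases, collapse = "")
    pos <- margin + spacing * (seq_len(config$n_sites) - 1L)  # 0-based
    for (p in pos) substr(seq, p + 1L, p + 2L) <- "CG"
    genome <- Biostrings::DNAStringSet(seq)
    names(genome) <- "chrS"
    sites <- data.frame(site_id = sprintf("s%04d", seq_len(config$n_sites)),
                        chrom = "chrS", start = as.integer(pos),
                        end = as.integer(pos) + 1L, class = cls,
                        stringsAsFactors = FALSE)
    list(genome = genome, sites = sites)
  })
}

#' Plant feature motifs into site windows
#'
#' For each site, each of the four fixed motifs (canonical G-quadruplex,
#' palindrome with 8 nt arms and 4 nt loop, PWM consensus, donor-site
#' consensus) is written into the site's window with the class-dependent
#' probability from the plan. Motif placements are fixed window-relative
#' offsets that never overlap each other or the central CpG; windows are
#' non-overlapping by construction, and a collision is an error.
#'
#' @param genome A one-chromosome [Biostrings::DNAStringSet].
#' @param sites Site table from [make_genome()].
#' @param plan Named list of per-class planting probabilities (scalar per
#'   class, or a named vector over `g4`, `pal`, `tfbs`, `donor`).
#' @param seed Integer seed.
#' @param offset Window half-width, default 50.
#' @return List with `genome` (modified) and `truth` (`data.frame`:
#'   `site_id`, `feature`, `start`, `end` in genome coordinates).
#' @export
plant_features <- function(genome, sites, plan, seed, offset = 50L) {
  chrom <- names(genome)[1]
  seq <- as.character(genome[[1]])
  L <- nchar(seq)
  feats <- names(PLANT_MOTIFS)
  rows <- list()
  occupied <- integer(0)
  withr_seed(seed, {
    for (i in seq_len(nrow(sites))) {
      p <- plan[[sites$class[i]]]
      if (is.null(p)) .stopf("plant_features: no plan for class '%s'", sites$class[i])
      pv <- if (length(p) == 1L) stats::setNames(rep(p, length(feats)), feats) else p
      ws <- sites$start[i] - offset
      for (f in feats) {
        if (stats::runif(1) > pv[[f]]) next
        motif <- PLANT_MOTIFS[[f]]
        s0 <- ws + PLANT_OFFSETS[[f]]                 # 0-based genome start
        e0 <- s0 + nchar(motif)
        if (s0 < 0L || e0 > L) .stopf("plant_features: motif outside genome at site %s",
                                      sites$site_id[i])
        span <- (s0 + 1L):e0
        if (any(span %in% occupied))
          .stopf("plant_features: window collision at site %s", sites$site_id[i])
        occupied <- c(occupied, span)
        substr(seq, s0 + 1L, e0) <- motif
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sites$site_id[i], feature = f, start = s0, end = e0,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- chrom
  truth <- if (length(rows)) do.call(rbind, rows)
           else data.frame(site_id = character(0), feature = character(0),
                           start = integer(0), end = integer(0),
                           stringsAsFactors = FALSE)
  list(genome = out, truth = truth)
}

#' Generate a bimodal beta matrix with designated differential sites
#'
#' Null sites draw both groups from one Beta mixture component (the
#' component chosen at random per site); differential sites draw the
#' control group from one component and shift the case group by the
#' configured \eqn{\Delta\beta} (clamped to \eqn{[0, 1]}): hypermethylated
#' sites start from the unmethylated mode and shift up, hypomethylated
#' sites start from the methylated mode and shift down.
#'
#' @param config A [sim_config()].
#' @param sites Site table (rows define the matrix rows).
#' @param differential Character vector of site ids to make differential
#'   (default none).
#' @param direction Named vector (+1 hyper / -1 hypo) per differential
#'   site; unnamed scalar recycled; default random signs.
#' @return A [beta_matrix()] with case group `"case"` (first level) and
#'   control `"ctrl"`; the per-site truth (`mode`, `differential`,
#'   `direction`) is attached as `attr(x, "truth")`.
#' @export
make_beta_matrix <- function(config, sites, differential = character(0),
                             direction = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(sites)
  ns <- config$n_samples_per_group
  lowp <- config$beta_modes$low; highp <- config$beta_modes$high
  withr_seed(config$seed + 1L, {
    is_diff <- sites$site_id %in% differential
    dir <- rep(0L, n)
    if (any(is_diff)) {
      if (is.null(direction)) {
        dir[is_diff] <- sample(c(-1L, 1L), sum(is_diff), replace = TRUE)
      } else if (is.null(names(direction))) {
        dir[is_diff] <- rep_len(direction, sum(is_diff))
      } else {
        dir[is_diff] <- direction[sites$site_id[is_diff]]
      }
    }
    mode <- ifelse(is_diff, ifelse(dir > 0, "low", "high"),
                   sample(c("low", "high"), n, replace = TRUE))
    vals <- matrix(NA_real_, nrow = n, ncol = 2L * ns)
    for (i in seq_len(n)) {
      par <- if (mode[i] == "low") lowp else highp
      ctrl <- stats::rbeta(ns, par[1], par[2])
      case <- stats::rbeta(ns, par[1], par[2])
      if (is_diff[i]) case <- pmin(1, pmax(0, case + dir[i] * config$effect))
      vals[i, ] <- c(case, ctrl)
    }
    colnames(vals) <- c(paste0("case_", seq_len(ns)), paste0("ctrl_", seq_len(ns)))
    rownames(vals) <- sites$site_id
    bm <- beta_matrix(vals, factor(rep(c("case", "ctrl"), each = ns),
                                   levels = c("case", "ctrl")),
                      sites = sites[, c("site_id", "chrom", "start", "end")])
    attr(bm, "truth") <- data.frame(site_id = sites$site_id, mode = mode,
                                    differential = is_diff, direction = dir,
                                    stringsAsFactors = FALSE)
    bm
  })
}

#' Generate an expression table coupled to planted feature load
#'
#' \eqn{|log_2FC|} = `coupling` x (number of planted features at the site)
#' + Gaussian noise (truncated at 0); the sign opposes the site's
#' \eqn{\Delta\beta} (hypermethylation pairs with down-regulation). Sites
#' without a \eqn{\Delta\beta} get a random sign.
#'
#' @param truth Planting truth table from [plant_features()].
#' @param sites Site table; a `delta_beta` column, if present, sets signs.
#' @param coupling Non-negative coupling coefficient.
#' @param noise_sd Gaussian noise standard deviation, default 0.1.
#' @param seed Integer seed.
#' @return `data.frame` with `site_id`, `gene`, `log2fc`, `n_planted`.
#' @export
make_expression_table <- function(truth, sites, coupling, noise_sd = 0.1, seed = 1L) {
  if (coupling < 0) .stopf("make_expression_table: coupling must be >= 0")
  counts <- table(truth$site_id)
  n_planted <- as.integer(counts[sites$site_id])
  n_planted[is.na(n_planted)] <- 0L
  withr_seed(seed, {
    mag <- pmax(0, coupling * n_planted + stats::rnorm(nrow(sites), 0, noise_sd))
    sgn <- if (!is.null(sites$delta_beta) && !all(is.na(sites$delta_beta)))
      ifelse(is.na(sites$delta_beta) | sites$delta_beta == 0,
             sample(c(-1, 1), nrow(sites), replace = TRUE),
             -sign(sites$delta_beta))
    else sample(c(-1, 1), nrow(sites), replace = TRUE)
    data.frame(site_id = sites$site_id,
               gene = paste0("gene_", sites$site_id),
               log2fc = sgn * mag, n_planted = n_planted,
               stringsAsFactors = FALSE)
  })
}

#' Run the full synthetic scenario
#'
#' Convenience wrapper: genome with classed sites, feature planting at the
#' configured class probabilities, and the bimodal beta matrix (enriched
#' and desert sites alike can be made differential via `differential`).
#'
#' @param config A [sim_config()].
#' @param differential Site ids to make differential in the beta matrix
#'   (default: all sites, signs random).
#' @return List with `genome`, `sites`, `truth`, `beta`.
#' @export
simulate_dataset <- function(config, differential = NULL) {
  g <- make_genome(config)
  pl <- plant_features(g$genome, g$sites, config$plant_prob,
                       seed = config$seed + 2L, offset = config$offset)
  if (is.null(differential)) differential <- g$sites$site_id
  bm <- make_beta_matrix(config, g$sites, differential = differential)
  list(genome = pl$genome, sites = g$sites, truth = pl$truth, beta = bm)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA (genome), BED4 (sites with class label), beta-matrix TSV,
#' two-column group annotation TSV, and the planting truth TSV.
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             sites = file.path(outdir, "sites.bed"),
             beta = file.path(outdir, "beta_matrix.tsv"),
             groups = file.path(outdir, "groups.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  utils::write.table(sim$sites[, c("chrom", "start", "end", "site_id", "class")],
                     paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bm <- data.frame(site_id = rownames(sim$beta$values), sim$beta$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(bm, paths["beta"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(colnames(sim$beta$values),
                                as.character(sim$beta$groups)),
                     paths["groups"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
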