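#' Illumina-like quality model
#'
#' Per-base quality decays quadratically with position: at 0-based position
#' n, Q(n) = q_start - decay * n^2, with intercept 37 for the 5'->3' profile
#' (read 1 and single-end reads) and 33 for the 3'->5' profile (read 2).
#' A constant-Q model (for calibration and testing) is available through
#' `constant`.
#'
#' @param q_start_fwd Intercept of the 5'->3' profile (default 37).
#' @param q_start_rev Intercept of the 3'->5' profile (default 33).
#' @param decay Quadratic decay per base^2 (default 1.88e-4).
#' @param constant Optional constant quality overriding the decay model.
#' @return An object of class `quality_model`.
#' @export
quality_model <- function(q_start_fwd = 37, q_start_rev = 33,
                          decay = 1.88e-4, constant = NULL) {
  structure(list(q_start_fwd = q_start_fwd, q_start_rev = q_start_rev,
                 decay = decay, constant = constant),
            class = "quality_model")
}

#' Quality at a read position
#'
#' @param model A [quality_model()].
#' @param n 0-based position(s) within the read.
#' @param direction `"5to3"` (read 1 / SE) or `"3to5"` (read 2).
#' @return Numeric quality value(s); an error if the model goes below 0 at
#'   any requested position.
#' @export
quality_at <- function(model, n, direction = c("5to3", "3to5")) {
  direction <- match.arg(direction)
  stopifnot(all(n >= 0))
  if (!is.null(model$constant)) return(rep(model$constant, length(n)))
  q0 <- if (direction == "5to3") model$q_start_fwd else model$q_start_rev
  q <- q0 - model$decay * n^2
  if (any(q < 0)) {
    stop("quality model drops below 0 at position ", min(n[q < 0]),
         "; requested read length exceeds the model's range")
  }
  q
}

#' Apply the sequencing-error process to a read
#'
#' Each input base draws u ~ Uniform(0,1) against its position's error
#' probability 10^(-Q(n)/10). A base that errors suffers exactly one event:
#' insertion of a random base before it (probability 0.05), deletion
#' (0.05), or substitution to one of the three other bases (0.90).
#' Positions n for the error draw are the input-base positions from the
#' read's own 5' end; emitted qualities follow the model over the *output*
#' positions, so inserted bases get the quality of the position they occupy.
#'
#' @param bases Read sequence over A/C/G/T.
#' @param model A [quality_model()].
#' @param direction Quality profile direction (see [quality_at()]).
#' @param error_free Skip the error draw (qualities still emitted).
#' @return List with `bases`, integer `qualities`, and `events` (named
#'   counts of insertion/deletion/mutation).
#' @export
introduce_errors <- function(bases, model = quality_model(),
                             direction = "5to3", error_free = FALSE) {
  b <- strsplit(bases, "")[[1]]
  n <- length(b)
  events <- c(insertion = 0L, deletion = 0L, mutation = 0L)
  if (n == 0 || error_free) {
    q <- if (n) round(quality_at(model, seq_len(n) - 1, direction)) else integer()
    return(list(bases = bases, qualities = as.integer(q), events = events))
  }
  p <- 10^(-quality_at(model, seq_len(n) - 1, direction) / 10)
  hit <- runif(n) < p
  out <- as.list(b)
  alphabet <- c("A", "C", "G", "T")
  for (i in which(hit)) {
    r <- runif(1)
    if (r < 0.05) {
      out[[i]] <- c(sample(alphabet, 1), b[i])
      events["insertion"] <- events["insertion"] + 1L
    } else if (r < 0.10) {
      out[[i]] <- character(0)
      events["deletion"] <- events["deletion"] + 1L
    } else {
      out[[i]] <- sample(setdiff(alphabet, b[i]), 1)
      events["mutation"] <- events["mutation"] + 1L
    }
  }
  res <- unlist(out)
  q <- if (length(res)) round(quality_at(model, seq_along(res) - 1, direction)) else integer()
  list(bases = paste(res, collapse = ""), qualities = as.integer(q),
       events = events)
}

#' Trim a read
#'
#' Removes `front` bases from the 5' end and `tail` bases from the 3' end
#' (both bases and qualities). Amplicon reads are trimmed 20 + 10 (primer
#' region plus low-quality tail); shotgun reads 10 + 10.
#'
#' @param bases Read sequence.
#' @param qualities Integer qualities, same length as `bases`.
#' @param front,tail Bases removed from each end.
#' @return List with trimmed `bases` and `qualities`, or `NULL` when the
#'   read is trimmed to empty (caller tallies the drop).
#' @export
trim_read <- function(bases, qualities, front = 20, tail = 10) {
  n <- nchar(bases)
  stopifnot(length(qualities) == n)
  if (n <= front + tail) return(NULL)
  list(bases = substr(bases, front + 1, n - tail),
       qualities = qualities[(front + 1):(n - tail)])
}

.amplicon_read_row <- function(raw, direction, model, error_free,
                               front = 20, tail = 10) {
  r <- introduce_errors(raw, model, direction, error_free)
  trim_read(r$bases, r$qualities, front, tail)
}

#' Simulate amplicon reads from one genome
#'
#' Finds amplicons of the configuration's primer pair, extracts SE or PE
#' reads, applies the error model (5'->3' profile for read 1 / SE, 3'->5'
#' for read 2), and trims 20 bp of primer region from the front and 10 bp
#' of low-quality tail from the end of every read.
#'
#' @param genome Nucleotide string or DNAString.
#' @param config An [amp_config()].
#' @param genome_id,species Provenance recorded with each read.
#' @param model A [quality_model()].
#' @param error_free Skip the error draw.
#' @param rep_index Replicate index used in read ids.
#' @param hits Optional precomputed [find_amplicons()] result.
#' @return List with `reads` (a [sim_reads()] frame) and `tallies` (named
#'   counts: `amplicon_too_short`, `trimmed_to_empty`).
#' @export
simulate_amplicon_reads <- function(genome, config, genome_id = "genome",
                                    species = NA_character_,
                                    model = quality_model(),
                                    error_free = FALSE, rep_index = 0L,
                                    hits = NULL) {
  if (is.null(hits)) {
    hits <- find_amplicons(genome, config$forward, config$reverse,
                           genome_id = genome_id)
  }
  tallies <- c(amplicon_too_short = 0L, trimmed_to_empty = 0L)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    rds <- extract_reads(hits$insert[i], config)
    if (is.null(rds)) {
      tallies["amplicon_too_short"] <- tallies["amplicon_too_short"] + 1L
      next
    }
    stem <- sprintf("%s|%d|%s.%d", genome_id, hits$copy_index[i],
                    species, rep_index)
    r1 <- .amplicon_read_row(rds$read1, "5to3", model, error_free)
    if (is.null(r1)) {
      tallies["trimmed_to_empty"] <- tallies["trimmed_to_empty"] + 1L
      next
    }
    if (config$layout == "PE") {
      r2 <- .amplicon_read_row(rds$read2, "3to5", model, error_free)
      if (is.null(r2)) {
        tallies["trimmed_to_empty"] <- tallies["trimmed_to_empty"] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- sim_reads(
        id = paste0(stem, c("/1", "/2")),
        bases = c(r1$bases, r2$bases),
        qualities = list(r1$qualities, r2$qualities),
        genome_id = genome_id, copy_index = hits$copy_index[i],
        species = species, end = c("R1", "R2"), config_label = config$label)
    } else {
      rows[[length(rows) + 1L]] <- sim_reads(
        id = stem, bases = r1$bases, qualities = list(r1$qualities),
        genome_id = genome_id, copy_index = hits$copy_index[i],
        species = species, end = "SE", config_label = config$label)
    }
  }
  reads <- if (length(rows)) do.call(rbind, rows) else sim_reads()
  list(reads = reads, tallies = tallies)
}

#' Simulate shotgun reads from a genome by a sliding window
#'
#' Windows start at position 0; each subsequent window starts at the end of
#' the previous one plus a random slide drawn uniformly from
#' `slide_range[1]:slide_range[2]` (default 0--2,000 bp). Each window yields
#' one single-end read; errors and qualities are applied as for amplicons,
#' then 10 bp are trimmed from each side. A window extending past the
#' genome end is discarded.
#'
#' @param genome Nucleotide string or DNAString.
#' @param read_length Window length in bp (before trimming).
#' @param genome_id,species Provenance recorded with each read.
#' @param model A [quality_model()].
#' @param error_free Skip the error draw.
#' @param slide_range Integer range of the random slide.
#' @param rep_index Replicate index used in read ids.
#' @return A [sim_reads()] data frame (possibly empty).
#' @export
simulate_shotgun <- function(genome, read_length, genome_id = "genome",
                             species = NA_character_,
                             model = quality_model(), error_free = FALSE,
                             slide_range = c(0, 2000), rep_index = 0L) {
  gseq <- toupper(as.character(genome))
  L <- nchar(gseq)
  rows <- list()
  s <- 0L
  k <- 0L
  while (s + read_length <= L) {
    raw <- substr(gseq, s + 1, s + read_length)
    r <- .amplicon_read_row(raw, "5to3", model, error_free,
                            front = 10, tail = 10)
    if (!is.null(r)) {
      rows[[length(rows) + 1L]] <- sim_reads(
        id = sprintf("%s|%d|%s.%d", genome_id, k, species, rep_index),
        bases = r$bases, qualities = list(r$qualities),
        genome_id = genome_id, copy_index = k, species = species,
        end = "SE", config_label = sprintf("shotgun SE %d bp", read_length))
    }
    k <- k + 1L
    s <- s + read_length + sample(slide_range[1]:slide_range[2], 1)
  }
  if (length(rows)) do.call(rbind, rows) else sim_reads()
}

#' Build a community design
#'
#' @param genome_id Genome ids.
#' @param replication Positive integer replication count per genome.
#' @param label Community label.
#' @return Data frame of class `community_design`.
#' @export
community_design <- function(genome_id, replication, label = "community") {
  stopifnot(length(genome_id) >= 1, length(replication) == length(genome_id),
            all(replication >= 1))
  structure(data.frame(genome_id = genome_id,
                       replication = as.integer(replication),
                       stringsAsFactors = FALSE),
            label = label, class = c("community_design", "data.frame"))
}

#' Simulate a whole community
#'
#' Each genome in the design is run `replication` times through the chosen
#' simulator. Two ground-truth species profiles are returned: the design
#' truth (relative abundance proportional to replication counts — the
#' target of copy-number-corrected profiling) and the copy-weighted truth
#' (additionally weighted by each genome's amplifiable 16S copy count —
#' what uncorrected read counting converges to).
#'
#' @param design A [community_design()] (columns `genome_id`, `replication`).
#' @param genomes Named DNAStringSet (or character vector) of genomes.
#' @param lineages Lineage table with an entry per genome id.
#' @param config An [amp_config()] for amplicon mode, or `NULL` with
#'   `shotgun_read_length` set for shotgun mode.
#' @param shotgun_read_length Read length for shotgun mode.
#' @param model A [quality_model()].
#' @param error_free Skip the error draw.
#' @return List with `reads`, `design_truth`, `copy_truth` (named species
#'   abundance vectors), and `tallies`.
#' @export
simulate_community <- function(design, genomes, lineages, config = NULL,
                               shotgun_read_length = NULL,
                               model = quality_model(), error_free = FALSE) {
  gseqs <- if (is(genomes, "XStringSet")) as.character(genomes) else genomes
  unknown <- setdiff(design$genome_id, names(gseqs))
  if (length(unknown)) {
    stop("design references unknown genome id(s): ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(config) && is.null(shotgun_read_length)) {
    stop("either an amp_config or a shotgun_read_length is required")
  }
  sp <- setNames(lineages$species, lineages$id)
  all_reads <- list()
  tallies <- c(amplicon_too_short = 0L, trimmed_to_empty = 0L)
  n_copies <- setNames(integer(nrow(design)), design$genome_id)
  for (i in seq_len(nrow(design))) {
    gid <- design$genome_id[i]
    if (!is.null(config)) {
      hits <- find_amplicons(gseqs[[gid]], config$forward, config$reverse,
                             genome_id = gid)
      n_copies[gid] <- nrow(hits)
      for (r in seq_len(design$replication[i])) {
        sim <- simulate_amplicon_reads(gseqs[[gid]], config, genome_id = gid,
                                       species = sp[[gid]], model = model,
                                       error_free = error_free,
                                       rep_index = r - 1L, hits = hits)
        all_reads[[length(all_reads) + 1L]] <- sim$reads
        tallies <- tallies + sim$tallies
      }
    } else {
      for (r in seq_len(design$replication[i])) {
        all_reads[[length(all_reads) + 1L]] <- simulate_shotgun(
          gseqs[[gid]], shotgun_read_length, genome_id = gid,
          species = sp[[gid]], model = model, error_free = error_free,
          rep_index = r - 1L)
      }
    }
  }
  reads <- if (length(all_reads)) do.call(rbind, all_reads) else sim_reads()
  w_design <- tapply(design$replication, sp[design$genome_id], sum)
  design_truth <- setNames(as.numeric(w_design) / sum(w_design), names(w_design))
  if (!is.null(config)) {
    w_copy <- design$replication * n_copies[design$genome_id]
  } else {
    w_copy <- design$replication * nchar(gseqs[design$genome_id])
  }
  w_copy <- tapply(w_copy, sp[design$genome_id], sum)
  copy_truth <- if (sum(w_copy) > 0) {
    setNames(as.numeric(w_copy) / sum(w_copy), names(w_copy))
  } else {
    setNames(numeric(0), character(0))
  }
  list(reads = reads, design_truth = design_truth, copy_truth = copy_truth,
       tallies = tallies)
}
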