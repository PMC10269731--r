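.check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1))) stop(what, " must be binary (0/1)")
  invisible(x)
}

#' Per-sequence completeness
#'
#' A sequence is complete under a configuration iff it is both amplified
#' (PAE = 1) and mapped to the reference at the identity cutoff (SMR = 1):
#' completeness = PAE x SMR.
#'
#' @param pae,smr Binary vectors (0/1).
#' @return Binary vector.
#' @export
completeness_flag <- function(pae, smr) {
  .check_binary(pae, "PAE"); .check_binary(smr, "SMR")
  pae * smr
}

.check_abd <- function(abd) {
  if (abs(sum(abd) - 1) > 1e-6) {
    stop("relative abundances must sum to 1 (got ", sum(abd), ")")
  }
  if (any(abd < 0)) stop("relative abundances must be non-negative")
  invisible(abd)
}

#' Abundance-weighted average sensitivity
#'
#' @param abd Per-sequence relative abundances (sum to 1).
#' @param completeness Per-sequence completeness flags.
#' @return Sum of abd * completeness.
#' @export
average_sensitivity <- function(abd, completeness) {
  .check_abd(abd)
  stopifnot(length(abd) == length(completeness))
  sum(abd * completeness)
}

#' Multitier precision of one sequence
#'
#' The fraction of the six scored ranks (phylum..species) annotated
#' correctly; a rank with no taxonomy counts as incorrect.
#'
#' @param correctness Binary vector of length 6, ordered phylum to species.
#' @return Value in [0, 1].
#' @export
sequence_precision <- function(correctness) {
  if (length(correctness) != length(lineage_ranks())) {
    stop("correctness must have exactly ", length(lineage_ranks()), " entries")
  }
  .check_binary(correctness, "correctness")
  mean(correctness)
}

#' Abundance-weighted average precision
#'
#' The precision mass of amplified-and-mapped sequences, renormalized by the
#' average sensitivity; 0 when nothing is amplified and mapped. Unmapped
#' sequences carry zero precision by the correctness rules, so the numerator
#' only ever receives mass from complete sequences.
#'
#' @param abd Per-sequence relative abundances (sum to 1).
#' @param completeness Per-sequence completeness flags.
#' @param precision Per-sequence multitier precision.
#' @return Value in [0, 1].
#' @export
average_precision <- function(abd, completeness, precision) {
  .check_abd(abd)
  stopifnot(length(abd) == length(completeness),
            length(abd) == length(precision))
  s <- sum(abd * completeness)
  if (s == 0) return(0)
  sum(abd * completeness * precision) / s
}

#' Sequencing cost term
#'
#' cost = 1000 / (1000 + effective length). By default the effective length
#' of a paired-end configuration is twice the read length (total sequenced
#' bases); `cost_length = "per-read"` uses the single-read length instead.
#'
#' @param config An [amp_config()], or directly an effective length in bp.
#' @param cost_length `"total"` or `"per-read"` (PE only distinction).
#' @return Value in (0, 1]; decreasing in effective length.
#' @export
seq_cost <- function(config, cost_length = c("total", "per-read")) {
  cost_length <- match.arg(cost_length)
  if (is.numeric(config)) {
    eff <- config
  } else {
    stopifnot(is(config, "amp_config"))
    eff <- config$read_length *
      (if (config$layout == "PE" && cost_length == "total") 2 else 1)
  }
  1000 / (1000 + eff)
}

#' Weighted Qscore
#'
#' @param sensitivity,precision,cost Component values in [0, 1].
#' @param weights Non-negative weights (w1, w2, w3), not all zero;
#'   default 1:1:1.
#' @return Weighted mean, in [0, 1].
#' @export
qscore <- function(sensitivity, precision, cost, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3)
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  comps <- c(sensitivity, precision, cost)
  stopifnot(all(comps >= 0), all(comps <= 1))
  sum(weights * comps) / sum(weights)
}

.locus_overlap <- function(hits, start, end) {
  which(hits$start < end & hits$end > start)
}

#' Enumerate 16S copy loci on genomes
#'
#' Copies are located primer-independently of any single short-read
#' configuration by merging amplicon hits of one or more locus-defining
#' primer pairs (default: the full-length 8F/1492R pair) into
#' non-overlapping loci per genome.
#'
#' @param genomes Named DNAStringSet or character vector.
#' @param pairs List of primer pairs (lists with `forward`, `reverse`).
#' @return Data frame: `genome_id`, `copy_index`, `start`, `end`.
#' @export
enumerate_16s_copies <- function(genomes, pairs = list(full_length_pair())) {
  gseqs <- if (is(genomes, "XStringSet")) as.character(genomes) else genomes
  rows <- list()
  for (gid in names(gseqs)) {
    ivs <- list()
    for (p in pairs) {
      h <- find_amplicons(gseqs[[gid]], p$forward, p$reverse, genome_id = gid)
      for (i in seq_len(nrow(h))) ivs[[length(ivs) + 1L]] <- c(h$start[i], h$end[i])
    }
    if (!length(ivs)) next
    m <- do.call(rbind, ivs)
    m <- m[order(m[, 1]), , drop = FALSE]
    merged <- list(m[1, ])
    for (i in seq_len(nrow(m))[-1]) {
      last <- merged[[length(merged)]]
      if (m[i, 1] < last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
      } else {
        merged[[length(merged) + 1L]] <- m[i, ]
      }
    }
    for (k in seq_along(merged)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, copy_index = k - 1L,
        start = merged[[k]][1], end = merged[[k]][2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(genome_id = character(), copy_index = integer(),
                      start = integer(), end = integer()))
  }
  do.call(rbind, rows)
}

#' Evaluate an amplification configuration end to end
#'
#' For every 16S copy locus: PAE is 1 iff the configuration's primer pair
#' yields an amplicon overlapping the locus; amplified copies are sequenced
#' in silico (error model, trimming, paired-end merging), annotated by best
#' hit against the reference, and scored for SMR and per-rank correctness
#' against the genome's true lineage. The components are then aggregated
#' into the weighted Qscore. A sequence that fails amplification, read
#' extraction, merging, or the identity cutoff has completeness 0 and
#' all-incorrect taxonomy.
#'
#' @param genomes Named DNAStringSet (or character) of genomes.
#' @param lineages Lineage table covering every genome id.
#' @param db A [reference_db()].
#' @param config An [amp_config()].
#' @param abd Optional relative abundances: named by `"genome|copy"` locus
#'   id or by genome id (split equally across a genome's copies). Default
#'   uniform over copies.
#' @param error_free Skip the sequencing-error draw.
#' @param model A [quality_model()].
#' @param copies Optional precomputed [enumerate_16s_copies()] table.
#' @param cutoff Best-hit identity cutoff.
#' @param weights Qscore weights (w1, w2, w3).
#' @param cost_length See [seq_cost()].
#' @return List with `breakdown` (one-row data frame: label, sensitivity,
#'   precision, cost, weights, qscore) and `per_sequence` (one row per 16S
#'   copy with abd, PAE, SMR, per-rank correctness, precision).
#' @export
evaluate_config <- function(genomes, lineages, db, config, abd = NULL,
                            error_free = FALSE, model = quality_model(),
                            copies = NULL, cutoff = 0.99,
                            weights = c(1, 1, 1),
                            cost_length = c("total", "per-read")) {
  cost_length <- match.arg(cost_length)
  gseqs <- if (is(genomes, "XStringSet")) as.character(genomes) else genomes
  miss <- setdiff(names(gseqs), lineages$id)
  if (length(miss)) stop("genomes without lineage: ", paste(miss, collapse = ", "))
  if (is.null(copies)) copies <- enumerate_16s_copies(gseqs)
  if (!nrow(copies)) stop("no 16S copy loci found on the given genomes")
  locus_id <- sprintf("%s|%d", copies$genome_id, copies$copy_index)

  if (is.null(abd)) {
    abd_vec <- rep(1 / nrow(copies), nrow(copies))
  } else if (all(names(abd) %in% locus_id)) {
    abd_vec <- unname(abd[locus_id]); abd_vec[is.na(abd_vec)] <- 0
  } else {
    per_g <- table(copies$genome_id)
    abd_vec <- unname(abd[copies$genome_id] / as.numeric(per_g[copies$genome_id]))
    abd_vec[is.na(abd_vec)] <- 0
  }
  if (sum(abd_vec) <= 0) stop("abundance vector assigns no mass to any 16S copy")
  abd_vec <- abd_vec / sum(abd_vec)

  index <- if (length(db) > 200) build_kmer_index(db) else NULL
  ranks <- lineage_ranks()
  n <- nrow(copies)
  pae <- integer(n); smr <- integer(n)
  corr <- matrix(0L, n, length(ranks), dimnames = list(NULL, ranks))

  for (gid in unique(copies$genome_id)) {
    rows_g <- which(copies$genome_id == gid)
    hits <- find_amplicons(gseqs[[gid]], config$forward, config$reverse,
                           genome_id = gid)
    truth <- unlist(lineages[match(gid, lineages$id), ranks])
    for (i in rows_g) {
      ov <- .locus_overlap(hits, copies$start[i], copies$end[i])
      if (!length(ov)) next
      pae[i] <- 1L
      rds <- extract_reads(hits$insert[ov[1]], config)
      if (is.null(rds)) next
      r1 <- .amplicon_read_row(rds$read1, "5to3", model, error_free)
      if (is.null(r1)) next
      if (config$layout == "PE") {
        r2 <- .amplicon_read_row(rds$read2, "3to5", model, error_free)
        if (is.null(r2)) next
        m <- merge_pairs(r1$bases, r2$bases, r1$qualities, r2$qualities)
        if (!m$merged) next
        query <- m$bases
      } else {
        query <- r1$bases
      }
      h <- best_hit(query, db, cutoff = cutoff, index = index)
      if (is.na(h$hit_id)) next
      smr[i] <- 1L
      corr[i, ] <- as.integer(h$predicted == truth & nzchar(truth) &
                                nzchar(h$predicted))
    }
  }

  comp <- completeness_flag(pae, smr)
  prec <- apply(corr, 1, mean)
  S <- average_sensitivity(abd_vec, comp)
  P <- average_precision(abd_vec, comp, prec)
  C <- seq_cost(config, cost_length)
  Q <- qscore(S, P, C, weights)
  per_seq <- data.frame(seq_id = locus_id, genome_id = copies$genome_id,
                        copy_index = copies$copy_index, abd = abd_vec,
                        pae = pae, smr = smr, completeness = comp,
                        corr, precision = prec, stringsAsFactors = FALSE)
  breakdown <- data.frame(config_label = config$label, sensitivity = S,
                          precision = P, cost = C, w1 = weights[1],
                          w2 = weights[2], w3 = weights[3], qscore = Q,
                          stringsAsFactors = FALSE)
  list(breakdown = breakdown, per_sequence = per_seq)
}

#' Compare a predicted profile to the truth at one rank
#'
#' Presence/absence and abundance agreement between two normalized profiles:
#' completeness (fraction of truth taxa recovered), purity (fraction of
#' predicted taxa that are real), L1 norm error, and Bray-Curtis
#' dissimilarity (L1/2 for normalized profiles).
#'
#' @param predicted,truth `tax_profile`s or named abundance vectors.
#' @param rank Rank to compare at (used when profiles are `tax_profile`s).
#' @return Named numeric: `completeness`, `purity`, `l1`, `bray_curtis`.
#' @export
compare_profiles <- function(predicted, truth, rank = "species") {
  get_vec <- function(p) {
    if (inherits(p, "tax_profile")) p <- p[[rank]]
    if (is.null(p) || !length(p)) return(setNames(numeric(0), character(0)))
    p[p > 0]
  }
  p <- get_vec(predicted); q <- get_vec(truth)
  if (!length(q)) stop("empty truth profile at rank ", rank)
  for (v in list(p, q)) {
    if (length(v) && abs(sum(v) - 1) > 1e-6) {
      stop("profiles must be normalized at rank ", rank)
    }
  }
  shared <- intersect(names(p), names(q))
  taxa <- union(names(p), names(q))
  pv <- setNames(rep(0, length(taxa)), taxa); pv[names(p)] <- p
  qv <- setNames(rep(0, length(taxa)), taxa); qv[names(q)] <- q
  l1 <- sum(abs(pv - qv))
  c(completeness = length(shared) / length(q),
    purity = if (length(p)) length(shared) / length(p) else 0,
    l1 = l1, bray_curtis = l1 / 2)
}
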