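#' Merge a read pair by its overlap
#'
#' Read 2 is reverse-complemented into insert orientation, then all overlap
#' offsets with at least `min_overlap` bases are scored; the offset
#' maximizing matched bases wins, subject to a mismatch ratio of at most
#' `max_mismatch_ratio` in the overlap. Disagreeing overlap bases are
#' resolved in favor of the higher-quality base. Merge failure is a
#' reported outcome (it costs sensitivity downstream), not an error.
#'
#' @param read1,read2 Read sequences; `read2` in sequencer orientation.
#' @param q1,q2 Integer quality vectors (defaults: flat 30).
#' @param min_overlap Minimum overlap length in bases.
#' @param max_mismatch_ratio Maximum fraction of mismatching overlap bases.
#' @return List with `merged` (logical); on success also `bases` and
#'   `qualities` of the merged read and `overlap`/`mismatches` diagnostics.
#' @export
merge_pairs <- function(read1, read2, q1 = NULL, q2 = NULL,
                        min_overlap = 10, max_mismatch_ratio = 0.25) {
  b1 <- strsplit(read1, "")[[1]]
  b2 <- strsplit(revcomp(read2), "")[[1]]
  n1 <- length(b1); n2 <- length(b2)
  if (is.null(q1)) q1 <- rep(30L, n1)
  if (is.null(q2)) q2 <- rep(30L, n2)
  stopifnot(length(q1) == n1, length(q2) == n2)
  q2 <- rev(q2)  # into insert orientation alongside revcomp
  best <- NULL
  for (o in seq_len(min(n1, n2))) {
    if (o < min_overlap) next
    s1 <- b1[(n1 - o + 1):n1]
    s2 <- b2[1:o]
    mm <- sum(s1 != s2)
    if (mm / o > max_mismatch_ratio) next
    matched <- o - mm
    if (is.null(best) || matched > best$matched ||
        (matched == best$matched && o > best$o)) {
      best <- list(o = o, mm = mm, matched = matched)
    }
  }
  if (is.null(best)) return(list(merged = FALSE))
  o <- best$o
  head_b <- b1[seq_len(n1 - o)]
  head_q <- q1[seq_len(n1 - o)]
  ov1 <- b1[(n1 - o + 1):n1]; ovq1 <- q1[(n1 - o + 1):n1]
  ov2 <- b2[1:o];             ovq2 <- q2[1:o]
  take2 <- (ov1 != ov2) & (ovq2 > ovq1)
  ov <- ifelse(take2, ov2, ov1)
  ovq <- pmax(ovq1, ovq2)
  tail_b <- if (o < n2) b2[(o + 1):n2] else character(0)
  tail_q <- if (o < n2) q2[(o + 1):n2] else integer(0)
  list(merged = TRUE,
       bases = paste(c(head_b, ov, tail_b), collapse = ""),
       qualities = as.integer(c(head_q, ovq, tail_q)),
       overlap = o, mismatches = best$mm)
}

.align_identity <- function(query, ref) {
  # semi-global: query end-gap free (global in query, local in reference);
  # identity = matching columns / alignment columns
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

.kmer_set <- function(seq, k = 8) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Build a k-mer prescreen index for a reference database
#'
#' @param db A [reference_db()].
#' @param k Word size.
#' @return Index object used by [best_hit()] to shortlist candidates.
#' @export
build_kmer_index <- function(db, k = 8) {
  sets <- lapply(as.character(db$seqs), .kmer_set, k = k)
  structure(list(k = k, sets = sets, ids = names(db$seqs)),
            class = "kmer_index")
}

#' Annotate a query sequence by best hit against the reference
#'
#' Aligns the query (both orientations) semi-globally against references and
#' reports the top hit by identity (matching columns over alignment
#' columns). Identity below the cutoff (inclusive at the cutoff) leaves the
#' query unclassified. Ties at equal identity are broken deterministically
#' by lexicographic record id and flagged ambiguous when the tied records
#' disagree on species. With an `index`, candidates are shortlisted to
#' references sharing at least one k-mer with the query (every reference is
#' aligned when the shortlist comes up empty).
#'
#' @param query Read sequence.
#' @param db A [reference_db()].
#' @param cutoff Identity cutoff (default 0.99, inclusive).
#' @param index Optional [build_kmer_index()] result.
#' @return List: `hit_id` (or `NA`), `identity`, `predicted` lineage (empty
#'   when unclassified), `ambiguous` flag.
#' @export
best_hit <- function(query, db, cutoff = 0.99, index = NULL) {
  stopifnot(is(db, "reference_db"))
  if (!nzchar(query)) stop("empty query sequence")
  if (length(db) == 0) stop("empty reference database")
  ids <- names(db$seqs)
  if (!is.null(index)) {
    qk <- unique(c(.kmer_set(query, index$k), .kmer_set(revcomp(query), index$k)))
    shared <- vapply(index$sets, function(s) any(qk %in% s), logical(1))
    if (any(shared)) ids <- index$ids[shared]
  }
  refs <- as.character(db$seqs[ids])
  qrc <- revcomp(query)
  idents <- vapply(refs, function(r) {
    max(.align_identity(query, r), .align_identity(qrc, r))
  }, numeric(1), USE.NAMES = FALSE)
  top <- max(idents)
  tied <- sort(ids[idents == top])
  hit <- tied[1]
  amb <- length(unique(db$lineages[tied, "species"])) > 1
  if (top < cutoff) {
    return(list(hit_id = NA_character_, identity = top,
                predicted = lineage(), ambiguous = FALSE))
  }
  list(hit_id = hit, identity = top,
       predicted = unlist(db$lineages[hit, lineage_ranks()]),
       ambiguous = amb)
}

#' Annotate a table of simulated reads
#'
#' Paired reads (ends `R1`/`R2` sharing a fragment id) are merged first;
#' pairs that fail to merge are reported unclassified (`merged = FALSE`),
#' mirroring the sensitivity loss of end-merging failure. Single-end reads
#' are aligned directly.
#'
#' @param reads A [sim_reads()] data frame.
#' @param db A [reference_db()].
#' @param cutoff Identity cutoff.
#' @param min_overlap,max_mismatch_ratio Merge parameters (see
#'   [merge_pairs()]).
#' @param use_index Build a k-mer prescreen index when the database has
#'   more than 200 records.
#' @return Data frame: `read_id`, `hit_id`, `identity`, `merged`, and the
#'   six predicted rank columns.
#' @export
annotate_reads <- function(reads, db, cutoff = 0.99, min_overlap = 10,
                           max_mismatch_ratio = 0.25, use_index = NULL) {
  if (is.null(use_index)) use_index <- length(db) > 200
  index <- if (use_index) build_kmer_index(db) else NULL
  frag <- sub("/[12]$", "", reads$id)
  out <- list()
  annotate_one <- function(read_id, bases, merged) {
    h <- best_hit(bases, db, cutoff = cutoff, index = index)
    data.frame(read_id = read_id, hit_id = h$hit_id, identity = h$identity,
               merged = merged, t(h$predicted), stringsAsFactors = FALSE)
  }
  for (f in unique(frag)) {
    rows <- reads[frag == f, , drop = FALSE]
    if (all(c("R1", "R2") %in% rows$end)) {
      r1 <- rows[rows$end == "R1", ][1, ]
      r2 <- rows[rows$end == "R2", ][1, ]
      m <- merge_pairs(r1$bases, r2$bases, r1$qualities[[1]], r2$qualities[[1]],
                       min_overlap, max_mismatch_ratio)
      if (m$merged) {
        out[[length(out) + 1L]] <- annotate_one(f, m$bases, TRUE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          read_id = f, hit_id = NA_character_, identity = NA_real_,
          merged = FALSE, t(lineage()), stringsAsFactors = FALSE)
      }
    } else {
      for (i in seq_len(nrow(rows))) {
        out[[length(out) + 1L]] <- annotate_one(rows$id[i], rows$bases[i], NA)
      }
    }
  }
  res <- do.call(rbind, out)
  names(res) <- c("read_id", "hit_id", "identity", "merged", lineage_ranks())
  rownames(res) <- NULL
  res
}

#' Build a taxonomic profile from per-read annotations
#'
#' Classified reads are counted by species; with copy-number correction,
#' each species' count is divided by its mean 16S copies per genome before
#' renormalizing. Higher ranks aggregate the species-level mass, and reads
#' classified only to a higher rank contribute at their deepest known rank.
#' Normalization is over classified reads only.
#'
#' @param annotations Result of [annotate_reads()].
#' @param db A [reference_db()] (source of copy numbers).
#' @param correct_copy_number Apply 16S copy-number correction.
#' @return A `tax_profile`: named list (per rank) of relative-abundance
#'   vectors, each summing to 1.
#' @export
profile_from_annotations <- function(annotations, db,
                                     correct_copy_number = TRUE) {
  cls <- annotations[!is.na(annotations$hit_id), , drop = FALSE]
  if (!nrow(cls)) {
    warning("no classified reads; returning empty profile")
    return(structure(setNames(vector("list", 6), lineage_ranks()),
                     class = "tax_profile"))
  }
  w <- rep(1, nrow(cls))
  if (correct_copy_number) {
    has_sp <- nzchar(cls$species)
    w[has_sp] <- 1 / copy_number(db, cls$species[has_sp], quiet = TRUE)
  }
  out <- lapply(lineage_ranks(), function(r) {
    tax <- cls[[r]]
    keep <- nzchar(tax)
    if (!any(keep)) return(setNames(numeric(0), character(0)))
    v <- tapply(w[keep], tax[keep], sum)
    v <- setNames(as.numeric(v), names(v))
    v / sum(v)
  })
  structure(setNames(out, lineage_ranks()), class = "tax_profile")
}

#' @export
print.tax_profile <- function(x, ...) {
  for (r in names(x)) {
    if (!length(x[[r]])) next
    cat(r, ": ", paste(sprintf("%s=%.4f", names(x[[r]]), x[[r]]),
                       collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
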