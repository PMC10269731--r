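#' Reference database container
#'
#' Bundles curated 16S reference sequences, their lineages, and per-species
#' mean 16S copy numbers. Copy numbers enter as metadata (the `copy_number`
#' column of the lineage table, averaged per species); they are expected to
#' come from a primer-independent count of annotated 16S loci so that
#' copy-number correction is not biased by amplification preference.
#'
#' @param seqs Named [Biostrings::DNAStringSet] (or character) of reference
#'   sequences.
#' @param lineages Data frame with columns `id`, the six ranks, and
#'   optionally `copy_number` (see [read_lineage_table()]).
#' @param copy_numbers Optional named numeric vector (species -> mean copies
#'   per genome); overrides values derived from `lineages`.
#' @return An object of class `reference_db`.
#' @export
reference_db <- function(seqs, lineages, copy_numbers = NULL) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0) {
    empty_lin <- data.frame(id = character(), stringsAsFactors = FALSE)
    for (r in lineage_ranks()) empty_lin[[r]] <- character()
    empty_lin$copy_number <- numeric()
    return(structure(list(seqs = seqs, lineages = empty_lin,
                          copy_numbers = setNames(numeric(0), character(0))),
                     class = "reference_db"))
  }
  if (is.null(names(seqs))) stop("reference sequences must be named")
  miss <- setdiff(names(seqs), lineages$id)
  if (length(miss)) {
    stop("records without lineage: ", paste(head(miss, 5), collapse = ", "))
  }
  lineages <- lineages[match(names(seqs), lineages$id), , drop = FALSE]
  rownames(lineages) <- lineages$id
  if (is.null(copy_numbers)) {
    cn <- lineages$copy_number
    if (!is.null(cn) && any(!is.na(cn))) {
      sp <- lineages$species
      ok <- !is.na(cn) & nzchar(sp)
      copy_numbers <- tapply(cn[ok], sp[ok], mean)
      copy_numbers <- setNames(as.numeric(copy_numbers), names(copy_numbers))
    } else {
      copy_numbers <- setNames(numeric(0), character(0))
    }
  }
  if (any(copy_numbers < 1)) stop("copy numbers must be >= 1")
  structure(
    list(seqs = seqs, lineages = lineages, copy_numbers = copy_numbers),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference_db:", length(x$seqs), "sequences,",
      length(unique(x$lineages$species[nzchar(x$lineages$species)])),
      "species,", length(x$copy_numbers), "species with copy-number data\n")
  invisible(x)
}

#' @export
length.reference_db <- function(x) length(x$seqs)

#' Curate a raw 16S reference set
#'
#' Applies the standard curation procedure: drop sequences shorter than
#' `min_len` (default 1,000 bp), then deduplicate at 100% sequence identity,
#' keeping one record (the first, which for byte-identical sequences is also
#' the longest) and its annotation. Identical sequences carrying conflicting
#' lineages are kept with the retained record's lineage and counted in the
#' report. Optionally, records that are exact substrings of a longer record
#' are also collapsed onto the longer record (`remove_contained = TRUE`,
#' off by default because 100%-identity clustering of equal-length
#' duplicates is the conventional behaviour).
#'
#' @param seqs Named DNAStringSet (or character) of raw reference sequences.
#' @param lineages Lineage table for `seqs`.
#' @param min_len Minimum sequence length retained.
#' @param remove_contained Collapse exact-substring records onto the longest.
#' @return List with `db` (a [reference_db()]) and `report` (named list with
#'   `input_count`, `dropped_short`, `dropped_duplicate`, `dropped_contained`,
#'   `lineage_conflicts`, `output_count`).
#' @export
curate_refdb <- function(seqs, lineages, min_len = 1000,
                         remove_contained = FALSE) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  n_in <- length(seqs)
  if (n_in == 0) {
    warning("empty reference input; returning empty database")
    db <- reference_db(Biostrings::DNAStringSet(),
                       data.frame(id = character()))
    return(list(db = db, report = list(
      input_count = 0L, dropped_short = 0L, dropped_duplicate = 0L,
      dropped_contained = 0L, lineage_conflicts = 0L, output_count = 0L)))
  }

  keep_len <- Biostrings::width(seqs) >= min_len
  dropped_short <- sum(!keep_len)
  seqs <- seqs[keep_len]

  # exact dedup: keep the first record of each identical-sequence group
  chr <- as.character(seqs)
  ord <- order(-nchar(chr))         # longest first (tautological for identical)
  first_idx <- ord[!duplicated(chr[ord])]
  first_idx <- sort(first_idx)
  dup_groups <- split(seq_along(chr), chr)
  conflicts <- 0L
  lin_by_id <- lineages[match(names(seqs), lineages$id), , drop = FALSE]
  for (g in dup_groups) {
    if (length(g) > 1) {
      lins <- apply(lin_by_id[g, lineage_ranks(), drop = FALSE], 1,
                    paste, collapse = ";")
      if (length(unique(lins)) > 1) {
        conflicts <- conflicts + 1L
        message("lineage conflict among identical sequences: ",
                paste(names(seqs)[g], collapse = ", "),
                "; keeping annotation of ", names(seqs)[min(g)])
      }
    }
  }
  dropped_dup <- length(seqs) - length(first_idx)
  seqs <- seqs[first_idx]

  dropped_contained <- 0L
  if (remove_contained && length(seqs) > 1) {
    chr <- as.character(seqs)
    ord <- order(nchar(chr))        # check short against longer
    contained <- logical(length(chr))
    for (k in seq_along(ord)) {
      i <- ord[k]
      longer <- ord[seq_along(ord) > k]
      longer <- longer[nchar(chr[longer]) > nchar(chr[i])]
      if (length(longer) &&
          any(vapply(chr[longer], function(s) grepl(chr[i], s, fixed = TRUE),
                     logical(1)))) {
        contained[i] <- TRUE
      }
    }
    dropped_contained <- sum(contained)
    seqs <- seqs[!contained]
  }

  lin_out <- lineages[match(names(seqs), lineages$id), , drop = FALSE]
  db <- reference_db(seqs, lin_out)
  list(db = db, report = list(
    input_count = n_in,
    dropped_short = dropped_short,
    dropped_duplicate = dropped_dup,
    dropped_contained = dropped_contained,
    lineage_conflicts = conflicts,
    output_count = length(seqs)))
}

#' Look up the 16S copy number of a species
#'
#' Returns the stored mean copies-per-genome; species without data fall back
#' to 1.0 (no correction) with a message.
#'
#' @param db A [reference_db()].
#' @param species Character vector of species names.
#' @param quiet Suppress the fallback message.
#' @return Numeric vector of copy numbers (>= 1).
#' @export
copy_number <- function(db, species, quiet = FALSE) {
  stopifnot(is(db, "reference_db"))
  out <- unname(db$copy_numbers[species])
  missing <- is.na(out)
  if (any(missing) && !quiet) {
    message("no copy-number data for ",
            paste(unique(species[missing]), collapse = ", "),
            "; using 1.0")
  }
  out[missing] <- 1.0
  out
}

#' Record ids of a species
#'
#' @param db A [reference_db()].
#' @param species Species name.
#' @return Character vector of record ids (possibly empty).
#' @export
species_records <- function(db, species) {
  db$lineages$id[db$lineages$species == species]
}

#' Write a reference database to a directory
#'
#' Writes `reference.fasta` and `lineage.tsv` (with copy_number column).
#'
#' @param db A [reference_db()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(db$seqs, file.path(dir, "reference.fasta"))
  lin <- db$lineages
  if (is.null(lin$copy_number) || all(is.na(lin$copy_number))) {
    lin$copy_number <- ifelse(nzchar(lin$species),
                              copy_number(db, lin$species, quiet = TRUE), NA_real_)
  }
  write_lineage_table(lin, file.path(dir, "lineage.tsv"))
  invisible(dir)
}

#' Read a reference database from a directory
#'
#' @param dir Directory written by [write_reference_db()].
#' @return A [reference_db()].
#' @export
read_reference_db <- function(dir) {
  seqs <- read_fasta(file.path(dir, "reference.fasta"))
  lin <- read_lineage_table(file.path(dir, "lineage.tsv"))
  reference_db(seqs, lin)
}
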