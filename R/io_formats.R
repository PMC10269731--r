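#' @importFrom methods is
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table head
NULL

.LINEAGE_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Scored taxonomic ranks
#'
#' The six ranks at which multitier annotation precision is scored, in
#' fixed order from phylum down to species.
#'
#' @return Character vector of rank names.
#' @export
lineage_ranks <- function() .LINEAGE_RANKS

#' Construct a lineage
#'
#' A lineage is a named character vector over the six scored ranks
#' (see [lineage_ranks()]). A missing rank is the empty string `""`,
#' never an arbitrary placeholder.
#'
#' @param phylum,class,order,family,genus,species Taxon names; default empty.
#' @return Named character vector of length 6.
#' @export
lineage <- function(phylum = "", class = "", order = "", family = "",
                    genus = "", species = "") {
  setNames(as.character(c(phylum, class, order, family, genus, species)),
           .LINEAGE_RANKS)
}

#' Parse a delimited lineage string
#'
#' Accepts both Greengenes-style strings (`"k__Bacteria;p__Firmicutes;..."`,
#' rank prefixes stripped) and plain semicolon-delimited strings. A leading
#' domain/kingdom field (7 fields total) is dropped; unknown or blank ranks
#' become the empty marker `""`.
#'
#' @param s Lineage string.
#' @return Named character vector of length 6 (see [lineage()]).
#' @export
#' @examples
#' parse_lineage("p__Firmicutes;c__;o__;f__;g__;s__")
parse_lineage <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (is.na(s) || !nzchar(trimws(s))) return(lineage())
  fields <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  if (length(fields) > 7) {
    stop("lineage string has ", length(fields), " fields; at most 7 allowed: ", s)
  }
  fields <- sub("^[dkpcofgs]__", "", fields)
  if (length(fields) == 7) fields <- fields[-1]  # drop domain/kingdom
  fields <- c(fields, rep("", 6 - length(fields)))
  setNames(fields, .LINEAGE_RANKS)
}

#' Serialize a lineage to a semicolon-delimited string
#'
#' @param lin Lineage (named character of length 6).
#' @return A single string; `parse_lineage()` of the result round-trips.
#' @export
format_lineage <- function(lin) {
  paste(as.character(lin[.LINEAGE_RANKS]), collapse = ";")
}

.check_bases <- function(x, where = "sequence") {
  bad <- grepl("[^ACGTRYMKSWHBVDN]", x)
  if (any(bad)) {
    stop("non-nucleotide characters in ", where, ": ",
         paste(head(names(x)[bad], 3), collapse = ", "))
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and RNA `U` is converted to `T`. Record ids are
#' the first whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file (optionally gzipped).
#' @return A [Biostrings::DNAStringSet] named by record id. An empty file
#'   yields an empty set.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- chartr("u", "t", toupper(as.character(x)))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[!nzchar(seqs)][1], "' in ", path)
  }
  names(seqs) <- ids
  .check_bases(seqs, paste0("FASTA file ", path))
  Biostrings::DNAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output file.
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(length(seqs))
}

#' Simulated-read table constructor
#'
#' Simulated reads are carried in a plain data frame with the ground-truth
#' provenance needed by downstream evaluation: source genome, 16S copy
#' index, true species, read end (`R1`/`R2`/`SE`) and configuration label.
#' Qualities are a list-column of integer Phred scores.
#'
#' @param id Read ids.
#' @param bases Character vector of read sequences.
#' @param qualities List of integer vectors, one per read.
#' @param genome_id,copy_index,species Ground-truth provenance.
#' @param end `"R1"`, `"R2"` or `"SE"`.
#' @param config_label Amplification configuration label.
#' @return `data.frame` with one row per read.
#' @export
sim_reads <- function(id = character(), bases = character(),
                      qualities = list(), genome_id = character(),
                      copy_index = integer(), species = character(),
                      end = character(), config_label = character()) {
  n <- length(id)
  stopifnot(length(bases) == n, length(qualities) == n)
  bad <- nchar(bases) != lengths(qualities)
  if (any(bad)) {
    stop("bases/qualities length mismatch for read(s): ",
         paste(head(id[bad], 3), collapse = ", "))
  }
  data.frame(
    id = id, bases = bases,
    qualities = I(qualities),
    genome_id = rep_len(if (n && length(genome_id)) genome_id else NA_character_, n),
    copy_index = rep_len(if (n && length(copy_index)) copy_index else NA_integer_, n),
    species = rep_len(if (n && length(species)) species else NA_character_, n),
    end = rep_len(if (n && length(end)) end else "SE", n),
    config_label = rep_len(if (n && length(config_label)) config_label else NA_character_, n),
    stringsAsFactors = FALSE
  )
}

.encode_phred <- function(q) {
  q <- round(q)
  if (any(q < 0 | q > 93)) stop("quality out of Phred+33 encodable range [0, 93]")
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1)) |>
    paste(collapse = "")
}

.decode_phred <- function(s) utf8ToInt(s) - 33L

#' Write simulated reads to FASTQ (Phred+33)
#'
#' Qualities are rounded to the nearest integer for encoding.
#'
#' @param reads A [sim_reads()] data frame.
#' @param path Output FASTQ file.
#' @return Invisibly, the number of reads written.
#' @export
write_fastq <- function(reads, path) {
  bad <- nchar(reads$bases) != lengths(reads$qualities)
  if (any(bad)) {
    stop("bases/qualities length mismatch for read(s): ",
         paste(head(reads$id[bad], 3), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(setNames(as.character(reads$bases), reads$id))
  quals <- Biostrings::BStringSet(vapply(reads$qualities, .encode_phred, character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(nrow(reads))
}

#' Read a FASTQ file into a simulated-read table
#'
#' Ground-truth provenance is recovered from read ids of the form
#' `genome|copy|species/end` when present.
#'
#' @param path FASTQ file.
#' @return A [sim_reads()] data frame.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(sim_reads())
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- lapply(as.character(S4Vectors::mcols(x)$qualities), .decode_phred)
  ids <- names(x)
  parts <- strsplit(sub("/[^/|]*$", "", ids), "|", fixed = TRUE)
  ends <- ifelse(grepl("/1$", ids), "R1", ifelse(grepl("/2$", ids), "R2", "SE"))
  sim_reads(
    id = ids, bases = as.character(x), qualities = quals,
    genome_id = vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, character(1)),
    copy_index = vapply(parts, function(p) {
      if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_
    }, integer(1)),
    species = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, character(1)),
    end = ends
  )
}

#' Read a lineage table
#'
#' Tab-separated with header `id<TAB>lineage[<TAB>copy_number]`. The lineage
#' column is parsed with [parse_lineage()]; `copy_number`, when present, must
#' be >= 1.
#'
#' @param path TSV file.
#' @return Data frame with columns `id`, the six ranks, and `copy_number`
#'   (NA when absent from the file).
#' @export
read_lineage_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "lineage") %in% names(df))) {
    stop("lineage table must have columns 'id' and 'lineage': ", path)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate ids in lineage table: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  lin <- t(vapply(df$lineage, parse_lineage, character(6)))
  out <- data.frame(id = df$id, lin, stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("id", .LINEAGE_RANKS)
  if ("copy_number" %in% names(df)) {
    cn <- as.numeric(df$copy_number)
    if (any(!is.na(cn) & cn < 1)) stop("copy_number values must be >= 1")
    out$copy_number <- cn
  } else {
    out$copy_number <- NA_real_
  }
  out
}

#' Write a lineage table
#'
#' @param lineages Data frame as returned by [read_lineage_table()].
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_lineage_table <- function(lineages, path) {
  lin <- apply(lineages[, .LINEAGE_RANKS, drop = FALSE], 1, paste, collapse = ";")
  out <- data.frame(id = lineages$id, lineage = lin)
  if (!is.null(lineages$copy_number) && any(!is.na(lineages$copy_number))) {
    out$copy_number <- lineages$copy_number
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a taxonomic profile to TSV
#'
#' One row per taxon: `rank<TAB>taxon<TAB>relative_abundance`. With
#' `rank` given, only that rank is written in two-column form
#' (`taxon<TAB>relative_abundance`).
#'
#' @param profile A `tax_profile` (see [profile_from_annotations()]) or a
#'   named numeric vector of relative abundances.
#' @param path Output TSV.
#' @param rank Optional single rank to write.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path, rank = NULL) {
  if (is.numeric(profile)) profile <- structure(list(species = profile), class = "tax_profile")
  if (!is.null(rank)) {
    v <- profile[[rank]]
    out <- data.frame(taxon = names(v), relative_abundance = as.numeric(v))
  } else {
    out <- do.call(rbind, lapply(names(profile), function(r) {
      v <- profile[[r]]
      if (!length(v)) return(NULL)
      data.frame(rank = r, taxon = names(v), relative_abundance = as.numeric(v))
    }))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomic profile TSV
#'
#' Accepts both the two-column (`taxon`, `relative_abundance`) and the long
#' three-column (`rank`, `taxon`, `relative_abundance`) layouts produced by
#' [write_profile()].
#'
#' @param path TSV file.
#' @param rank Rank assigned to two-column input (default `"species"`).
#' @return A `tax_profile`: named list of per-rank abundance vectors.
#' @export
read_profile <- function(path, rank = "species") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("rank" %in% names(df)) {
    ranks <- intersect(.LINEAGE_RANKS, unique(df$rank))
    out <- lapply(ranks, function(r) {
      sub <- df[df$rank == r, ]
      setNames(sub$relative_abundance, sub$taxon)
    })
    structure(setNames(out, ranks), class = "tax_profile")
  } else {
    structure(setNames(list(setNames(df$relative_abundance, df$taxon)), rank),
              class = "tax_profile")
  }
}
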