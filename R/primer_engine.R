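.IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", M = "AC", K = "GT", S = "CG", W = "AT",
  H = "ACT", B = "CGT", V = "ACG", D = "AGT", N = "ATCG"
)

#' Convert an IUPAC-degenerate oligo to a regular expression
#'
#' Literal bases pass through; degenerate codes become character classes
#' (`R -> [AG]`, `Y -> [CT]`, ..., `N -> [ATCG]`). Matching against genome
#' text with this expression is exact: ambiguity codes in the *genome* are
#' treated as literal characters and never match a primer class.
#'
#' @param iupac Primer sequence over the IUPAC alphabet.
#' @return Regular expression string.
#' @export
#' @examples
#' iupac_to_regex("AGRGTTYGATYNTGGCTCAG")
iupac_to_regex <- function(iupac) {
  stopifnot(is.character(iupac), length(iupac) == 1, nzchar(iupac))
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- !(chars %in% names(.IUPAC_CLASSES))
  if (any(bad)) {
    stop("invalid IUPAC character '", chars[which(bad)[1]], "' at position ",
         which(bad)[1], " in primer ", iupac)
  }
  paste(vapply(chars, function(ch) {
    cls <- .IUPAC_CLASSES[[ch]]
    if (nchar(cls) == 1) cls else paste0("[", cls, "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of a (possibly degenerate) sequence
#'
#' @param x Nucleotide string over the IUPAC alphabet.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Define an amplification primer
#'
#' @param name Primer name, e.g. `"515F"`.
#' @param iupac Primer sequence over the IUPAC alphabet.
#' @param direction `"forward"` or `"reverse"`.
#' @return An object of class `primer_def`.
#' @export
primer_def <- function(name, iupac, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  iupac <- toupper(iupac)
  iupac_to_regex(iupac)  # validates
  structure(list(name = name, iupac = iupac, direction = direction),
            class = "primer_def")
}

#' @export
print.primer_def <- function(x, ...) {
  cat(sprintf("primer %s (%s): %s\n", x$name, x$direction, x$iupac))
  invisible(x)
}

#' Built-in amplification primers
#'
#' The thirteen primers shipped with the package, covering the V1--V9
#' regions of the 16S rRNA gene.
#'
#' @return Data frame with columns `name`, `sequence`, `direction`.
#' @export
builtin_primers <- function() {
  read.delim(system.file("extdata", "primers.tsv", package = "qscorekit"),
             stringsAsFactors = FALSE)
}

.primer_by_name <- function(name) {
  tab <- builtin_primers()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown primer: ", name)
  primer_def(tab$name[i], tab$sequence[i], tab$direction[i])
}

#' Define an amplification + sequencing configuration
#'
#' Labels follow the "variable region + sequence type + sequence length"
#' convention, e.g. `"V4 PE 150 bp"`.
#'
#' @param label Configuration label.
#' @param forward,reverse [primer_def()] objects (or built-in primer names).
#' @param layout `"SE"` or `"PE"`.
#' @param read_length Read length in bp; one of 100, 150, 250, 300.
#' @param region Variable-region label, e.g. `"V4"`.
#' @return An object of class `amp_config`.
#' @export
amp_config <- function(label, forward, reverse, layout = c("SE", "PE"),
                       read_length, region = NA_character_) {
  layout <- match.arg(layout)
  if (is.character(forward)) forward <- .primer_by_name(forward)
  if (is.character(reverse)) reverse <- .primer_by_name(reverse)
  stopifnot(is(forward, "primer_def"), is(reverse, "primer_def"))
  read_length <- as.integer(read_length)
  if (!(read_length %in% c(100L, 150L, 250L, 300L))) {
    stop("read_length must be one of 100, 150, 250, 300 bp")
  }
  structure(list(label = label, forward = forward, reverse = reverse,
                 layout = layout, read_length = read_length, region = region),
            class = "amp_config")
}

#' @export
print.amp_config <- function(x, ...) {
  cat(sprintf("config '%s': %s/%s, %s %d bp\n", x$label, x$forward$name,
              x$reverse$name, x$layout, x$read_length))
  invisible(x)
}

#' Built-in amplification configurations
#'
#' The 32 short-read primer-set configurations shipped with the package.
#'
#' @return Data frame with columns `label`, `region`, `forward`, `reverse`,
#'   `layout`, `read_length`.
#' @export
builtin_configs <- function() {
  read.delim(system.file("extdata", "configs.tsv", package = "qscorekit"),
             stringsAsFactors = FALSE)
}

#' Fetch a built-in configuration by label
#'
#' @param label A label from [builtin_configs()], e.g. `"V4 PE 150 bp"`.
#' @return An [amp_config()].
#' @export
builtin_config <- function(label) {
  tab <- builtin_configs()
  i <- match(label, tab$label)
  if (is.na(i)) {
    stop("unknown configuration '", label, "'; see builtin_configs()")
  }
  amp_config(tab$label[i], tab$forward[i], tab$reverse[i], tab$layout[i],
             tab$read_length[i], tab$region[i])
}

#' Full-length 16S primer pair
#'
#' The 8F/1492R pair spanning (nearly) the whole gene; used to enumerate
#' 16S copies independently of any short-read configuration.
#'
#' @return List with elements `forward` and `reverse` ([primer_def()]s).
#' @export
full_length_pair <- function() {
  list(forward = .primer_by_name("8F"), reverse = .primer_by_name("1492R"))
}

#' Locate primer binding sites on a sequence
#'
#' All match positions are reported, including overlapping matches at
#' distinct starts. With `orientation = "revcomp"` the reverse complement of
#' the primer is matched (the binding site of a reverse primer on the
#' forward strand), coordinates still on the given sequence.
#'
#' @param primer A [primer_def()] or IUPAC string.
#' @param seq Uppercase nucleotide string (or DNAString).
#' @param orientation `"as-is"` or `"revcomp"`.
#' @return Data frame with 0-based half-open `start`, `end` columns.
#' @export
match_primer <- function(primer, seq, orientation = c("as-is", "revcomp")) {
  orientation <- match.arg(orientation)
  iupac <- if (is(primer, "primer_def")) primer$iupac else toupper(primer)
  if (orientation == "revcomp") iupac <- revcomp(iupac)
  rx <- iupac_to_regex(iupac)
  seq <- as.character(seq)
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  start0 <- as.integer(m) - 1L
  data.frame(start = start0, end = start0 + nchar(iupac))
}

.pair_sites <- function(fwd_sites, rev_sites, max_insert) {
  hits <- list()
  used <- rep(FALSE, nrow(rev_sites))
  if (nrow(fwd_sites)) fwd_sites <- fwd_sites[order(fwd_sites$start), , drop = FALSE]
  for (i in seq_len(nrow(fwd_sites))) {
    fs <- fwd_sites$start[i]; fe <- fwd_sites$end[i]
    cand <- which(!used & rev_sites$start >= fe &
                    rev_sites$end - fs <= max_insert)
    if (!length(cand)) next
    j <- cand[which.min(rev_sites$start[cand])]
    used[j] <- TRUE
    hits[[length(hits) + 1L]] <- c(fs, fe, rev_sites$start[j], rev_sites$end[j])
  }
  hits
}

#' Find amplicons of a primer pair on a genome
#'
#' The forward primer is matched as written and the reverse primer as its
#' reverse complement; each forward site is paired with the nearest
#' downstream reverse site within `max_insert` (each reverse site used at
#' most once). Both strands are searched; inserts are always reported 5'->3'
#' with respect to the forward primer and include both primer sites.
#' `fwd_start`..`rev_end` are 0-based half-open coordinates on the scanned
#' strand; `start`/`end` project the full insert onto the forward strand of
#' the stored sequence regardless of strand.
#'
#' @param genome Nucleotide string or DNAString.
#' @param fwd,rev [primer_def()]s (or IUPAC strings).
#' @param max_insert Maximum insert length in bp (primer sites included).
#' @param genome_id Id recorded in the output.
#' @return Data frame with one row per amplicon hit: `genome_id`, `strand`,
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end`, `start`, `end`,
#'   `insert`, `copy_index` (0-based per genome).
#' @export
find_amplicons <- function(genome, fwd, rev, max_insert = 3000,
                           genome_id = "genome") {
  gseq <- toupper(as.character(genome))
  L <- nchar(gseq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") gseq else revcomp(gseq)
    fs <- match_primer(fwd, s, "as-is")
    rs <- match_primer(rev, s, "revcomp")
    for (h in .pair_sites(fs, rs, max_insert)) {
      ins <- substr(s, h[1] + 1, h[4])
      proj <- if (strand == "+") c(h[1], h[4]) else c(L - h[4], L - h[1])
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genome_id, strand = strand,
        fwd_start = h[1], fwd_end = h[2], rev_start = h[3], rev_end = h[4],
        start = proj[1], end = proj[2], insert = ins,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(genome_id = character(), strand = character(),
                      fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      start = integer(), end = integer(),
                      insert = character(), copy_index = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  out$copy_index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

#' Extract fixed-length reads from an amplicon insert
#'
#' Single-end: the first `read_length` bases of the insert, starting at the
#' forward primer's 5' end. Paired-end: additionally `read_length` bases
#' ending at the reverse primer's 3' end, reverse-complemented into read
#' (sequencer) orientation. Reads never extend past the opposite primer's
#' outer boundary: an insert shorter than the read length yields `NULL`
#' (the caller tallies the skip).
#'
#' @param insert Amplicon insert sequence (primers included).
#' @param config An [amp_config()].
#' @return List with `read1` and (PE only) `read2`, or `NULL` if the insert
#'   is too short.
#' @export
extract_reads <- function(insert, config) {
  n <- nchar(insert)
  rl <- config$read_length
  if (n < rl) return(NULL)
  read1 <- substr(insert, 1, rl)
  if (config$layout == "SE") return(list(read1 = read1))
  list(read1 = read1, read2 = revcomp(substr(insert, n - rl + 1, n)))
}
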