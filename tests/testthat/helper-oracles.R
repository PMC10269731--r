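# Independent oracles used across tests. These deliberately avoid the
# package's own matching/alignment code paths.

# IUPAC semantics straight from the degenerate-code table
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("G", "C"), W = c("A", "T"),
  H = c("A", "T", "C"), B = c("G", "T", "C"), V = c("G", "A", "C"),
  D = c("G", "A", "T"), N = c("A", "G", "C", "T")
)

# enumerate every concrete expansion of a degenerate oligo
oracle_expansions <- function(iupac) {
  sets <- ORACLE_IUPAC[strsplit(iupac, "")[[1]]]
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1,
        paste, collapse = "")
}

# brute-force window scan: all 0-based half-open windows of |primer| whose
# bases each fall in the corresponding IUPAC class
oracle_scan <- function(iupac, seq) {
  k <- nchar(iupac)
  sets <- ORACLE_IUPAC[strsplit(iupac, "")[[1]]]
  n <- nchar(seq)
  hits <- list()
  for (s in seq_len(max(n - k + 1, 0))) {
    win <- strsplit(substr(seq, s, s + k - 1), "")[[1]]
    if (all(mapply(function(b, cls) b %in% cls, win, sets))) {
      hits[[length(hits) + 1L]] <- c(s - 1L, s - 1L + k)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], end = m[, 2])
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", M = "K",
            K = "M", S = "S", W = "W", H = "D", B = "V", V = "B", D = "H",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# small reference database built directly (no curation path)
toy_db <- function(seqs, species = names(seqs), copy_numbers = NULL,
                   genus = "Genus_1") {
  lin <- data.frame(id = names(seqs),
                    phylum = "P1", class = "C1", order = "O1",
                    family = "F1", genus = genus, species = species,
                    copy_number = NA_real_, stringsAsFactors = FALSE)
  reference_db(seqs, lin, copy_numbers = copy_numbers)
}
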