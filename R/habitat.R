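#' Filter a per-sample OTU count table
#'
#' Within each sample, OTUs with relative abundance below 0.01% (1e-4) or a
#' sequence count below 10 are zeroed out. Samples with a zero total are
#' skipped with a warning.
#'
#' @param counts Long data frame with columns `sample`, `otu`, `count` (an
#'   optional `config` column is carried through).
#' @param min_abundance Relative-abundance floor (default 1e-4).
#' @param min_count Count floor (default 10).
#' @return The filtered data frame, with a `"drop_report"` attribute giving
#'   per-sample dropped-OTU counts.
#' @export
filter_otus <- function(counts, min_abundance = 1e-4, min_count = 10) {
  stopifnot(all(c("sample", "otu", "count") %in% names(counts)),
            all(counts$count >= 0))
  report <- integer(0)
  for (s in unique(counts$sample)) {
    rows <- which(counts$sample == s)
    tot <- sum(counts$count[rows])
    if (tot == 0) {
      warning("sample '", s, "' has zero total count; skipped")
      next
    }
    drop <- counts$count[rows] < min_count |
      counts$count[rows] / tot < min_abundance
    counts$count[rows[drop]] <- 0
    report[s] <- sum(drop)
  }
  attr(counts, "drop_report") <- report
  counts
}

#' Pool filtered per-sample counts into an OTU x configuration matrix
#'
#' @param counts Long data frame with columns `otu`, `config`, `count`.
#' @return Integer matrix, rows = OTU ids, columns = configuration labels.
#' @export
pool_counts <- function(counts) {
  stopifnot(all(c("otu", "config", "count") %in% names(counts)))
  tab <- tapply(counts$count, list(counts$otu, counts$config), sum,
                default = 0)
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Primer compatibility indicator
#'
#' comp(x) = 0 if x <= 0, else 1: an OTU is compatible with a configuration
#' iff that configuration observed it at all.
#'
#' @param x Numeric vector.
#' @return Integer 0/1 vector.
#' @export
comp_positive <- function(x) as.integer(x > 0)

#' Estimate OTU richness from a multi-configuration count table
#'
#' For OTU i: richness(i) = sum_j count(i,j) divided by the summed
#' sequencing depth (column totals) of only those configurations j
#' compatible with i (comp(count(i,j)) = 1). An OTU absent from every
#' configuration has richness 0. Richness is invariant to rescaling all
#' counts by a common factor.
#'
#' @param table Count matrix (rows OTUs, columns configurations) as from
#'   [pool_counts()].
#' @return Named numeric vector of richness values.
#' @export
otu_richness <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  if (all(colSums(table) == 0)) stop("count table has no positive column total")
  col_tot <- colSums(table)
  vapply(seq_len(nrow(table)), function(i) {
    num <- sum(table[i, ])
    den <- sum(comp_positive(table[i, ]) * col_tot)
    if (den == 0) 0 else num / den
  }, numeric(1)) |> setNames(rownames(table))
}

#' Habitat-specific OTU relative abundance
#'
#' Normalizes [otu_richness()] to sum to 1.
#'
#' @param table Count matrix (rows OTUs, columns configurations).
#' @return Named numeric vector summing to 1.
#' @export
habitat_abundance <- function(table) {
  r <- otu_richness(table)
  if (all(r == 0)) stop("all OTUs have zero richness; cannot normalize")
  r / sum(r)
}

#' Rank amplification configurations for a habitat
#'
#' Runs [evaluate_config()] with the habitat's OTU abundances injected and
#' reports every configuration's Qscore under two weight presets: the
#' default (sensitivity : precision : cost, typically 1:1:1) and the
#' cost-free preset (w3 = 0, "regardless of cost"). OTUs that do not
#' resolve to a genome are dropped with a warning when they carry less than
#' 5% of the abundance mass, and are an error otherwise.
#'
#' @param abd Named OTU abundance vector (from [habitat_abundance()]).
#' @param otu_map Data frame mapping `otu` to `genome_id`.
#' @param genomes,lineages,db,... Passed to [evaluate_config()].
#' @param configs List of [amp_config()]s (or labels of built-in configs).
#' @param weights Primary weight preset.
#' @return Data frame, one row per configuration, sorted by primary Qscore
#'   descending: label, sensitivity, precision, cost, `qscore`,
#'   `qscore_no_cost`, and both ranks.
#' @export
rank_configs_for_habitat <- function(abd, otu_map, genomes, lineages, db,
                                     configs, weights = c(1, 1, 1), ...) {
  stopifnot(all(c("otu", "genome_id") %in% names(otu_map)))
  hit <- names(abd) %in% otu_map$otu
  if (!all(hit)) {
    lost <- sum(abd[!hit])
    if (lost >= 0.05) {
      stop("unresolvable OTU ids carry ", round(lost * 100, 1),
           "% of abundance mass: ", paste(names(abd)[!hit], collapse = ", "))
    }
    warning("dropping unresolvable OTU ids (",
            paste(names(abd)[!hit], collapse = ", "), "; ",
            round(lost * 100, 2), "% of mass)")
    abd <- abd[hit] / sum(abd[hit])
  }
  gid <- otu_map$genome_id[match(names(abd), otu_map$otu)]
  g_abd <- tapply(abd, gid, sum)
  g_abd <- setNames(as.numeric(g_abd), names(g_abd))
  gseqs <- if (is(genomes, "XStringSet")) as.character(genomes) else genomes
  copies <- enumerate_16s_copies(gseqs)
  rows <- lapply(configs, function(cf) {
    if (is.character(cf)) cf <- builtin_config(cf)
    ev <- evaluate_config(gseqs, lineages, db, cf, abd = g_abd,
                          copies = copies, weights = weights, ...)
    b <- ev$breakdown
    w_nc <- if (weights[1] + weights[2] > 0) c(weights[1], weights[2], 0)
            else c(1, 1, 0)
    b$qscore_no_cost <- qscore(b$sensitivity, b$precision, b$cost, w_nc)
    b
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$qscore), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rank_no_cost <- rank(-out$qscore_no_cost, ties.method = "first")
  rownames(out) <- NULL
  out
}

#' Read an OTU x configuration count table from TSV
#'
#' Rows are OTU ids (first column `otu`), remaining columns configuration
#' labels with integer counts.
#'
#' @param path TSV file.
#' @return Numeric matrix with OTU rownames.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative counts in ", path)
  m
}
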