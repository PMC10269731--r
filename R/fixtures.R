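# Synthetic 16S gene layout. Conserved blocks are concrete expansions of the
# built-in primer binding motifs laid out with realistic geometry: as on the
# real gene, the 341F site contains the 357R binding site, the 515F site is
# the 518R binding site, and the U789F site sits inside the 806R site, so a
# single conserved block serves both primers. Variable blocks carry the
# species signal.
.FIXTURE_LAYOUT <- list(
  list(name = "c_8F",    type = "conserved", seq = "AGAGTTTGATCCTGGCTCAG"),
  list(name = "V1V2",    type = "variable",  len = 300L),
  list(name = "c_341",   type = "conserved", seq = "CCTACGGGAGGCAGCAG"),
  list(name = "V3",      type = "variable",  len = 140L),
  list(name = "c_515",   type = "conserved", seq = "GTGCCAGCAGCCGCGGTAA"),
  list(name = "V4",      type = "variable",  len = 230L),
  list(name = "c_789",   type = "conserved", seq = "ATTAGATACCCTGGTAGTCC"),
  list(name = "V5",      type = "variable",  len = 90L),
  list(name = "c_926",   type = "conserved", seq = "AAACTCAAATGAATTGACGG"),
  list(name = "s_967",   type = "variable",  len = 20L),
  list(name = "c_967",   type = "conserved", seq = "CAACGCGAAGAACCTTACC"),
  list(name = "V6",      type = "variable",  len = 100L),
  list(name = "c_1064",  type = "conserved", seq = "AGGTGCTGCATGGCTGTCG"),
  list(name = "s_1099",  type = "variable",  len = 20L),
  list(name = "c_1099",  type = "conserved", seq = "GCAACGAGCGCAACCC"),
  list(name = "V7V8",    type = "variable",  len = 300L),
  list(name = "c_1406",  type = "conserved", seq = "TGTACACACCGCCCGTC"),
  list(name = "V9",      type = "variable",  len = 60L),
  list(name = "c_1492",  type = "conserved", seq = "AAGTCGTAACAAGGTA")
)

.fixture_variable_names <- function() {
  vapply(Filter(function(b) b$type == "variable", .FIXTURE_LAYOUT),
         `[[`, character(1), "name")
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

.assemble_16s <- function(regions) {
  paste(vapply(.FIXTURE_LAYOUT, function(blk) {
    if (blk$type == "conserved") blk$seq else regions[[blk$name]]
  }, character(1)), collapse = "")
}

.base_variable_regions <- function() {
  vn <- .fixture_variable_names()
  lens <- vapply(Filter(function(b) b$type == "variable", .FIXTURE_LAYOUT),
                 `[[`, integer(1), "len")
  setNames(lapply(lens, .random_bases), vn)
}

.fixture_lineage <- function(i, genus_idx) {
  phy <- paste0("Synthophyla_", ((i - 1) %% 2) + 1)
  lineage(
    phylum = phy,
    class = paste0("Synthoclassia_", ((i - 1) %% 2) + 1),
    order = paste0("Synthorales_", genus_idx),
    family = paste0("Synthaceae_", genus_idx),
    genus = paste0("Synthogenus_", genus_idx),
    species = sprintf("Synthogenus_%d_species_%02d", genus_idx, i)
  )
}

.validate_fixture_genome <- function(genome, n_copies) {
  for (pair in list(full_length_pair())) {
    hits <- find_amplicons(genome, pair$forward, pair$reverse)
    if (nrow(hits) != n_copies) {
      stop("fixture generation produced ", nrow(hits), " full-length 16S ",
           "amplicons instead of ", n_copies,
           "; the divergence spec destroyed a primer site")
    }
  }
  invisible(TRUE)
}

#' Generate synthetic fixture genomes with embedded 16S genes
#'
#' Builds a set of species genomes, each embedding one or more identical
#' copies of a synthetic ~1.4-kb 16S rRNA gene: conserved primer-site blocks
#' shared by all species (concrete expansions of the built-in primers, with
#' realistic overlap geometry) interleaved with species-specific variable
#' regions. Each species' variable regions are derived from a common
#' ancestral template by independent per-base substitution at the requested
#' divergence, so primer sites are never disturbed. The returned truth table
#' records the exact coordinates and lineage of every embedded copy.
#'
#' @param n_species Number of species (one genome per species).
#' @param copies_per_genome Integer; either a single count or a range
#'   `c(lo, hi)` sampled per species.
#' @param divergence Per-base substitution probability applied to each
#'   variable region, either a single value or a named vector over the
#'   variable-region names (`V1V2`, `V3`, `V4`, `V5`, `V6`, `V7V8`, `V9`,
#'   plus spacers `s_967`, `s_1099`). Naming a conserved block is an error:
#'   divergence there would destroy primer sites.
#' @param background_range Range of random intergenic background lengths.
#' @param n_genera Number of genera the species are assigned to.
#' @return List with `genomes` (named DNAStringSet), `lineages` (lineage
#'   table with `copy_number` = embedded copies), and `truth` (data frame
#'   `genome_id`, `copy_index`, `start`, `end` 0-based half-open, `species`).
#' @export
generate_fixture_genomes <- function(n_species = 5, copies_per_genome = 2,
                                     divergence = 0.08,
                                     background_range = c(200, 400),
                                     n_genera = n_species) {
  stopifnot(n_species >= 1)
  vn <- .fixture_variable_names()
  if (is.null(names(divergence))) {
    divergence <- setNames(rep(divergence[1], length(vn)), vn)
  } else {
    bad <- setdiff(names(divergence), vn)
    if (length(bad)) {
      stop("divergence names a non-variable block (", paste(bad, collapse = ", "),
           "); mutating conserved blocks would destroy primer sites")
    }
    full <- setNames(rep(0, length(vn)), vn)
    full[names(divergence)] <- divergence
    divergence <- full
  }
  base <- .base_variable_regions()
  n_copies <- if (length(copies_per_genome) == 1) {
    rep(as.integer(copies_per_genome), n_species)
  } else {
    sample(copies_per_genome[1]:copies_per_genome[2], n_species, replace = TRUE)
  }
  genomes <- character(n_species)
  ids <- sprintf("fixture_genome_%02d", seq_len(n_species))
  lin_rows <- list()
  truth_rows <- list()
  for (i in seq_len(n_species)) {
    regions <- setNames(lapply(vn, function(r) {
      .mutate_bases(base[[r]], divergence[[r]])
    }), vn)
    gene <- .assemble_16s(regions)
    parts <- character(0)
    pos <- 0L
    for (k in seq_len(n_copies[i])) {
      bg <- .random_bases(sample(background_range[1]:background_range[2], 1))
      parts <- c(parts, bg, gene)
      pos <- pos + nchar(bg)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        genome_id = ids[i], copy_index = k - 1L,
        start = pos, end = pos + nchar(gene),
        stringsAsFactors = FALSE)
      pos <- pos + nchar(gene)
    }
    parts <- c(parts, .random_bases(sample(background_range[1]:background_range[2], 1)))
    genomes[i] <- paste(parts, collapse = "")
    genus_idx <- ((i - 1L) %% n_genera) + 1L
    lin <- .fixture_lineage(i, genus_idx)
    lin_rows[[i]] <- data.frame(id = ids[i], t(lin), copy_number = n_copies[i],
                                stringsAsFactors = FALSE)
    .validate_fixture_genome(genomes[i], n_copies[i])
  }
  lineages <- do.call(rbind, lin_rows)
  names(lineages) <- c("id", lineage_ranks(), "copy_number")
  truth <- do.call(rbind, truth_rows)
  truth$species <- lineages$species[match(truth$genome_id, lineages$id)]
  list(genomes = Biostrings::DNAStringSet(setNames(genomes, ids)),
       lineages = lineages, truth = truth)
}

#' Generate a species pair differing in a single variable region
#'
#' Two congeneric species whose 16S genes are identical everywhere except
#' one variable region, where they diverge at the given rate. Reads covering
#' only the shared regions cannot separate the pair; reads covering the
#' divergent region can — the construction used to show that the optimal
#' amplification region depends on which taxa must be discriminated.
#'
#' @param region_divergent Variable region in which the pair differs.
#' @param divergence Per-base substitution rate in the divergent region.
#' @param copies_per_genome Identical 16S copies embedded per genome.
#' @param background_range Range of random background lengths.
#' @return Same structure as [generate_fixture_genomes()].
#' @export
generate_divergent_pair <- function(region_divergent = "V4",
                                    divergence = 0.10,
                                    copies_per_genome = 1,
                                    background_range = c(200, 400)) {
  vn <- .fixture_variable_names()
  if (!(region_divergent %in% vn)) {
    stop("region_divergent must be one of: ", paste(vn, collapse = ", "))
  }
  base <- .base_variable_regions()
  regions_b <- base
  regions_b[[region_divergent]] <-
    .mutate_bases(base[[region_divergent]], divergence)
  if (identical(regions_b[[region_divergent]], base[[region_divergent]])) {
    stop("divergence too low: the pair's ", region_divergent,
         " regions came out identical")
  }
  genes <- c(.assemble_16s(base), .assemble_16s(regions_b))
  ids <- c("fixture_pair_A", "fixture_pair_B")
  genomes <- character(2)
  truth_rows <- list()
  for (i in 1:2) {
    parts <- character(0)
    pos <- 0L
    for (k in seq_len(copies_per_genome)) {
      bg <- .random_bases(sample(background_range[1]:background_range[2], 1))
      parts <- c(parts, bg, genes[i])
      pos <- pos + nchar(bg)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        genome_id = ids[i], copy_index = k - 1L,
        start = pos, end = pos + nchar(genes[i]), stringsAsFactors = FALSE)
      pos <- pos + nchar(genes[i])
    }
    parts <- c(parts, .random_bases(sample(background_range[1]:background_range[2], 1)))
    genomes[i] <- paste(parts, collapse = "")
    .validate_fixture_genome(genomes[i], copies_per_genome)
  }
  lin <- rbind(
    data.frame(id = ids[1], t(.fixture_lineage(1, 1)),
               copy_number = copies_per_genome, stringsAsFactors = FALSE),
    data.frame(id = ids[2], t(.fixture_lineage(2, 1)),
               copy_number = copies_per_genome, stringsAsFactors = FALSE)
  )
  names(lin) <- c("id", lineage_ranks(), "copy_number")
  # congeneric pair: same lineage through genus, distinct species epithets
  lin[2, c("phylum", "class", "order", "family", "genus")] <-
    lin[1, c("phylum", "class", "order", "family", "genus")]
  truth <- do.call(rbind, truth_rows)
  truth$species <- lin$species[match(truth$genome_id, lin$id)]
  list(genomes = Biostrings::DNAStringSet(setNames(genomes, ids)),
       lineages = lin, truth = truth)
}

#' Build a 16S reference database from fixture truth
#'
#' Extracts every embedded 16S copy verbatim from the fixture genomes and
#' curates them into a [reference_db()] (identical within-genome copies
#' collapse to one record per species).
#'
#' @param fixture Result of [generate_fixture_genomes()].
#' @param min_len Curation length filter.
#' @return A [reference_db()].
#' @export
fixture_reference_db <- function(fixture, min_len = 1000) {
  truth <- fixture$truth
  seqs <- substr(as.character(fixture$genomes[truth$genome_id]),
                 truth$start + 1, truth$end)
  ids <- sprintf("%s_16S_%d", truth$genome_id, truth$copy_index)
  lin <- fixture$lineages[match(truth$genome_id, fixture$lineages$id), ]
  lin$id <- ids
  curate_refdb(setNames(seqs, ids), lin, min_len = min_len)$db
}
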