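# independent brute-force semi-global aligner (affine gaps, match 1,
# mismatch -1, open 4, extend 2 — the implementation's scoring scheme),
# maximizing score; identity = matches / alignment columns. Query end-gap
# free is realized by free leading/trailing reference columns.
oracle_semiglobal_identity <- function(query, ref) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  nq <- length(q); nr <- length(r)
  NEG <- -1e9
  # dp over query rows; three states: M (diag), X (gap in ref/consume query),
  # Y (gap in query/consume ref). Track matches alongside score.
  sc_m <- matrix(NEG, nq + 1, nr + 1); mt_m <- matrix(0, nq + 1, nr + 1)
  sc_x <- matrix(NEG, nq + 1, nr + 1); mt_x <- matrix(0, nq + 1, nr + 1)
  sc_y <- matrix(NEG, nq + 1, nr + 1); mt_y <- matrix(0, nq + 1, nr + 1)
  cl_m <- matrix(0, nq + 1, nr + 1); cl_x <- cl_m; cl_y <- cl_m
  sc_m[1, ] <- 0  # free start anywhere in reference
  for (i in 2:(nq + 1)) {
    for (j in 1:(nr + 1)) {
      # X: query base i-1 against a gap
      opens <- c(sc_m[i - 1, j] - 4 - 2, sc_x[i - 1, j] - 2,
                 sc_y[i - 1, j] - 4 - 2)
      k <- which.max(opens)
      sc_x[i, j] <- opens[k]
      mt_x[i, j] <- c(mt_m[i - 1, j], mt_x[i - 1, j], mt_y[i - 1, j])[k]
      cl_x[i, j] <- c(cl_m[i - 1, j], cl_x[i - 1, j], cl_y[i - 1, j])[k] + 1
      if (j > 1) {
        s <- if (q[i - 1] == r[j - 1]) 1 else -1
        prev <- c(sc_m[i - 1, j - 1], sc_x[i - 1, j - 1], sc_y[i - 1, j - 1])
        k <- which.max(prev)
        sc_m[i, j] <- prev[k] + s
        mt_m[i, j] <- c(mt_m[i - 1, j - 1], mt_x[i - 1, j - 1],
                        mt_y[i - 1, j - 1])[k] + (s == 1)
        cl_m[i, j] <- c(cl_m[i - 1, j - 1], cl_x[i - 1, j - 1],
                        cl_y[i - 1, j - 1])[k] + 1
        opens <- c(sc_m[i, j - 1] - 4 - 2, sc_x[i, j - 1] - 4 - 2,
                   sc_y[i, j - 1] - 2)
        k <- which.max(opens)
        sc_y[i, j] <- opens[k]
        mt_y[i, j] <- c(mt_m[i, j - 1], mt_x[i, j - 1], mt_y[i, j - 1])[k]
        cl_y[i, j] <- c(cl_m[i, j - 1], cl_x[i, j - 1], cl_y[i, j - 1])[k] + 1
      }
    }
  }
  # free end anywhere in reference
  finals <- rbind(cbind(as.vector(sc_m[nq + 1, ]), as.vector(mt_m[nq + 1, ]),
                        as.vector(cl_m[nq + 1, ])),
                  cbind(as.vector(sc_x[nq + 1, ]), as.vector(mt_x[nq + 1, ]),
                        as.vector(cl_x[nq + 1, ])))
  best <- finals[which.max(finals[, 1]), ]
  list(score = best[1], identity = best[2] / best[3])
}

test_that("paired-end merging reconstructs the insert from its overlap", {
  set.seed(71)
  insert <- random_dna(400)
  r1 <- substr(insert, 1, 250)
  r2 <- revcomp(substr(insert, 151, 400))
  m <- merge_pairs(r1, r2)
  expect_true(m$merged)
  expect_equal(m$bases, insert)
  expect_equal(m$overlap, 100)
  expect_equal(m$mismatches, 0)
})

test_that("merging fails without overlap or beyond the mismatch ratio", {
  set.seed(72)
  insert <- random_dna(600)
  m <- merge_pairs(substr(insert, 1, 250),
                   revcomp(substr(insert, 351, 600)))
  expect_false(m$merged)

  # overlap 100 with 30 planted mismatches (ratio 0.30 > 0.25)
  insert <- random_dna(400)
  r1 <- substr(insert, 1, 250)
  tail_part <- substr(insert, 151, 400)
  mut <- strsplit(tail_part, "")[[1]]
  pos <- seq(2, 90, 3)[1:30]  # inside the overlap region 1..100 of tail_part
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  m2 <- merge_pairs(r1, revcomp(paste(mut, collapse = "")))
  expect_false(isTRUE(m2$merged) && m2$overlap >= 90)
})

test_that("overlap disagreements resolve toward the higher-quality base", {
  set.seed(73)
  insert <- random_dna(60)
  r1 <- substr(insert, 1, 40)
  r2_seq <- substr(insert, 21, 60)
  # corrupt one overlap base on read 1 and give read 2 higher quality there
  b1 <- strsplit(r1, "")[[1]]
  b1[30] <- setdiff(c("A", "C", "G", "T"), b1[30])[1]
  r1_bad <- paste(b1, collapse = "")
  m <- merge_pairs(r1_bad, revcomp(r2_seq),
                   q1 = rep(20L, 40), q2 = rep(35L, 40))
  expect_true(m$merged)
  expect_equal(m$bases, insert)
})

test_that("best_hit identity agrees with the brute-force aligner", {
  set.seed(74)
  ref <- random_dna(300)
  db <- toy_db(c(refA = ref), species = "sp A")
  # exact containment
  h <- best_hit(substr(ref, 51, 150), db)
  expect_equal(h$identity, 1.0)
  expect_equal(h$hit_id, "refA")
  expect_equal(unname(h$predicted["species"]), "sp A")

  # 2 substitutions in a 100-base query -> 0.98 < 0.99: unclassified
  q <- strsplit(substr(ref, 51, 150), "")[[1]]
  q[10] <- setdiff(c("A", "C", "G", "T"), q[10])[1]
  q[60] <- setdiff(c("A", "C", "G", "T"), q[60])[1]
  q <- paste(q, collapse = "")
  h2 <- best_hit(q, db)
  expect_equal(h2$identity, 0.98)
  expect_true(is.na(h2$hit_id))
  expect_equal(unname(h2$predicted), rep("", 6))
  expect_equal(oracle_semiglobal_identity(q, ref)$identity, 0.98)

  # oracle agreement across random mutated queries
  for (i in 1:5) {
    qq <- strsplit(substr(ref, 21, 170), "")[[1]]
    for (p in sample(150, 4)) qq[p] <- sample(setdiff(c("A", "C", "G", "T"), qq[p]), 1)
    qq <- paste(qq, collapse = "")
    expect_equal(best_hit(qq, db, cutoff = 0)$identity,
                 oracle_semiglobal_identity(qq, ref)$identity)
  }
})

test_that("ties break lexicographically and flag ambiguity", {
  set.seed(75)
  shared <- random_dna(200)
  db <- toy_db(c(refB = paste0(shared, random_dna(50)),
                 refA = paste0(random_dna(50), shared)),
               species = c("sp B", "sp A"))
  h <- best_hit(substr(shared, 11, 110), db)
  expect_equal(h$identity, 1.0)
  expect_equal(h$hit_id, "refA")  # lexicographically smaller id
  expect_true(h$ambiguous)
})

test_that("reads align in both orientations", {
  set.seed(76)
  ref <- random_dna(300)
  db <- toy_db(c(r1 = ref), species = "sp")
  h <- best_hit(revcomp(substr(ref, 101, 200)), db)
  expect_equal(h$identity, 1.0)
})

test_that("prescreened best_hit equals the exhaustive scan on a 50-record db", {
  set.seed(77)
  refs <- setNames(vapply(1:50, function(i) random_dna(250), character(1)),
                   sprintf("ref%02d", 1:50))
  db <- toy_db(refs, species = sprintf("sp %02d", 1:50))
  index <- build_kmer_index(db)
  for (i in 1:8) {
    src <- sample(50, 1)
    q <- strsplit(substr(refs[src], 51, 180), "")[[1]]
    for (p in sample(130, 2)) q[p] <- sample(setdiff(c("A", "C", "G", "T"), q[p]), 1)
    q <- paste(q, collapse = "")
    fast <- best_hit(q, db, cutoff = 0, index = index)
    slow <- best_hit(q, db, cutoff = 0, index = NULL)
    expect_equal(fast$hit_id, slow$hit_id)
    expect_equal(fast$identity, slow$identity)
  }
})

test_that("error-free fixture reads annotate to the true species", {
  set.seed(78)
  fx <- generate_fixture_genomes(4, 2, divergence = 0.08)
  db <- fixture_reference_db(fx)
  des <- community_design(fx$lineages$id, rep(1, 4))
  sim <- simulate_community(des, fx$genomes, fx$lineages,
                            config = builtin_config("V4 PE 150 bp"),
                            error_free = TRUE)
  ann <- annotate_reads(sim$reads, db)
  expect_true(all(!is.na(ann$hit_id)))
  truth_sp <- sim$reads$species[sim$reads$end == "R1"]
  expect_equal(ann$species, truth_sp)
  expect_true(all(ann$identity == 1))
  expect_true(all(ann$merged))
})

test_that("profiles apply copy-number correction and sum to one per rank", {
  set.seed(79)
  db <- toy_db(c(rA = random_dna(200), rB = random_dna(200)),
               species = c("sp A", "sp B"),
               copy_numbers = c("sp A" = 3, "sp B" = 1))
  ann <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    hit_id = rep(c("rA", "rB"), c(60, 40)),
    identity = 1, merged = NA,
    phylum = "P1", class = "C1", order = "O1", family = "F1",
    genus = "Genus_1",
    species = rep(c("sp A", "sp B"), c(60, 40)),
    stringsAsFactors = FALSE)
  corrected <- profile_from_annotations(ann, db, correct_copy_number = TRUE)
  # (60/3) : (40/1) = 20 : 40
  expect_equal(unname(corrected$species[c("sp A", "sp B")]), c(1 / 3, 2 / 3))
  raw <- profile_from_annotations(ann, db, correct_copy_number = FALSE)
  expect_equal(unname(raw$species[c("sp A", "sp B")]), c(0.6, 0.4))
  for (r in lineage_ranks()) {
    expect_equal(sum(corrected[[r]]), 1)
    expect_equal(sum(raw[[r]]), 1)
  }
  # aggregation: both species share the genus
  expect_equal(unname(corrected$genus["Genus_1"]), 1)

  single <- profile_from_annotations(ann[1:10, ], db)
  expect_equal(unname(single$species["sp A"]), 1)

  none <- ann[1:2, ]
  none$hit_id <- NA_character_
  expect_warning(p0 <- profile_from_annotations(none, db), "no classified")
  expect_true(all(lengths(p0) == 0))
})
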