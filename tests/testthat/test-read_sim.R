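test_that("quality model follows the quadratic decay for both profiles", {
  m <- quality_model()
  expect_equal(quality_at(m, 0, "5to3"), 37)
  expect_equal(quality_at(m, 0, "3to5"), 33)
  expect_equal(quality_at(m, 200, "5to3"), 37 - 1.88e-4 * 200^2)  # 29.48
  expect_equal(quality_at(m, 200, "5to3"), 29.48)
  # model-range guard
  expect_error(quality_at(m, 500, "5to3"), "below 0")
})

test_that("error-free mode returns the input verbatim with model qualities", {
  set.seed(61)
  b <- random_dna(150)
  r <- introduce_errors(b, quality_model(), error_free = TRUE)
  expect_equal(r$bases, b)
  expect_equal(r$qualities, as.integer(round(37 - 1.88e-4 * (0:149)^2)))
  expect_equal(sum(r$events), 0)
})

test_that("substitutions never reproduce the original base", {
  set.seed(62)
  # constant Q = 0 forces an event at every base; with the 5/5/90 split most
  # are substitutions
  b <- random_dna(500)
  r <- introduce_errors(b, quality_model(constant = 0))
  expect_equal(sum(r$events), 500)
  # reconstruct positions without indels to compare: run again keeping only
  # mutations by construction is not possible, so check via a mutation-heavy
  # draw on single bases
  for (i in 1:50) {
    out <- introduce_errors("A", quality_model(constant = 0))
    if (out$events["mutation"] == 1) expect_false(out$bases == "A")
  }
})

test_that("empirical error rate matches the binomial oracle at constant Q", {
  set.seed(63)
  n <- 1e5
  p <- 1e-3  # Q = 30
  r <- introduce_errors(random_dna(n), quality_model(constant = 30))
  total <- sum(r$events)
  expect_lt(abs(total - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("trimming removes exact base counts and drops empty reads", {
  set.seed(64)
  b <- random_dna(150)
  q <- rep(30L, 150)
  tr <- trim_read(b, q, front = 20, tail = 10)
  expect_equal(nchar(tr$bases), 120)
  expect_equal(tr$bases, substr(b, 21, 140))
  expect_length(tr$qualities, 120)
  expect_null(trim_read(random_dna(30), rep(30L, 30), 20, 10))
  tr1 <- trim_read(random_dna(31), rep(30L, 31), 20, 10)
  expect_equal(nchar(tr1$bases), 1)
})

test_that("shotgun windows advance by read_length plus slide", {
  set.seed(65)
  g <- random_dna(10000)
  reads <- simulate_shotgun(g, 150, slide_range = c(0, 0), error_free = TRUE)
  expect_equal(nrow(reads), 66)  # floor(10000 / 150)
  # shotgun trimming removes 10 + 10
  expect_true(all(nchar(reads$bases) == 130))
  expect_equal(reads$bases[2], substr(g, 151 + 10, 300 - 10))
  # genome shorter than the window yields nothing
  expect_equal(nrow(simulate_shotgun(random_dna(100), 150)), 0)
})

test_that("community simulation is proportional, decomposable and seeded", {
  set.seed(66)
  fx <- generate_fixture_genomes(2, 1, divergence = 0.05)
  cf <- builtin_config("V4 SE 150 bp")
  des <- community_design(fx$lineages$id, c(2, 1))
  sim <- simulate_community(des, fx$genomes, fx$lineages, config = cf,
                            error_free = TRUE)
  counts <- table(sim$reads$genome_id)
  expect_equal(unname(counts[fx$lineages$id[1]] / counts[fx$lineages$id[2]]), 2)
  expect_equal(unname(sim$design_truth[fx$lineages$species]),
               c(2 / 3, 1 / 3))

  # determinism: identical FASTQ bytes under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  set.seed(123)
  s1 <- simulate_community(des, fx$genomes, fx$lineages, config = cf)
  write_fastq(s1$reads, f1)
  set.seed(123)
  s2 <- simulate_community(des, fx$genomes, fx$lineages, config = cf)
  write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(
    simulate_community(community_design("nope", 1), fx$genomes, fx$lineages,
                       config = cf),
    "unknown genome id")
})

test_that("copy multiplicity feeds reads but not the design truth", {
  set.seed(67)
  fx <- generate_fixture_genomes(1, 3, divergence = 0)
  cf <- builtin_config("V4 SE 150 bp")
  des <- community_design(fx$lineages$id, 1)
  sim <- simulate_community(des, fx$genomes, fx$lineages, config = cf,
                            error_free = TRUE)
  expect_equal(nrow(sim$reads), 3)
  expect_equal(unname(sim$design_truth), 1.0)
})

test_that("fixture generator embeds recoverable 16S copies deterministically", {
  set.seed(68)
  fx <- generate_fixture_genomes(3, 2, divergence = 0.08)
  expect_equal(nrow(fx$truth), 6)
  cf <- builtin_config("V4 PE 150 bp")
  for (gid in names(fx$genomes)) {
    h <- find_amplicons(as.character(fx$genomes[[gid]]), cf$forward,
                        cf$reverse)
    expect_equal(nrow(h), 2)
  }
  set.seed(68)
  fx2 <- generate_fixture_genomes(3, 2, divergence = 0.08)
  expect_identical(as.character(fx$genomes), as.character(fx2$genomes))

  expect_error(generate_fixture_genomes(2, 1, divergence = c(c_8F = 0.5)),
               "conserved")
})

test_that("divergent-pair fixtures differ only in the chosen region", {
  set.seed(69)
  fx <- generate_divergent_pair("V4", divergence = 0.10)
  pair <- full_length_pair()
  g16 <- vapply(names(fx$genomes), function(gid) {
    find_amplicons(as.character(fx$genomes[[gid]]), pair$forward,
                   pair$reverse)$insert[1]
  }, character(1))
  expect_false(g16[1] == g16[2])
  # identical outside V4: V6 amplicons (967F/1064R) coincide
  cf6 <- builtin_config("V6 PE 100 bp")
  v6 <- vapply(names(fx$genomes), function(gid) {
    find_amplicons(as.character(fx$genomes[[gid]]), cf6$forward,
                   cf6$reverse)$insert[1]
  }, character(1))
  expect_equal(unname(v6[1]), unname(v6[2]))
  # divergent inside V4
  cf4 <- builtin_config("V4 PE 150 bp")
  v4 <- vapply(names(fx$genomes), function(gid) {
    find_amplicons(as.character(fx$genomes[[gid]]), cf4$forward,
                   cf4$reverse)$insert[1]
  }, character(1))
  expect_false(v4[1] == v4[2])
})
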