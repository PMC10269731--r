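test_that("iupac_to_regex reproduces the 8F worked example", {
  expect_equal(iupac_to_regex("AGRGTTYGATYNTGGCTCAG"),
               "AG[AG]GTT[CT]GAT[CT][ATCG]TGGCTCAG")
  expect_equal(iupac_to_regex("ACGT"), "ACGT")
  expect_error(iupac_to_regex("ACXT"), "position 3")
})

test_that("character classes agree with the code table as sets", {
  # NRY: cross-check by enumerating all 16 concrete trimers
  rx <- iupac_to_regex("NRY")
  exps <- oracle_expansions("NRY")
  expect_length(exps, 16)
  for (e in exps) expect_true(grepl(paste0("^", rx, "$"), e))
  # class content equality regardless of ordering convention
  classes <- regmatches(rx, gregexpr("\\[[A-Z]+\\]", rx))[[1]]
  expect_setequal(strsplit(gsub("\\[|\\]", "", classes[1]), "")[[1]],
                  c("A", "T", "C", "G"))
})

test_that("match_primer reports all overlapping starts (window-scan oracle)", {
  expect_equal(match_primer("AR", "TAAG"),
               data.frame(start = c(1L, 2L), end = c(3L, 4L)))
  expect_equal(nrow(match_primer("CCC", "ATATAT")), 0)
  # revcomp orientation: revcomp(AAA) = TTT
  expect_equal(match_primer("AAA", "TTTG", orientation = "revcomp"),
               data.frame(start = 0, end = 3))

  set.seed(51)
  for (primer in c("AR", "NRY", "GGWCC")) {
    for (rep in 1:5) {
      s <- random_dna(60)
      got <- match_primer(primer, s)
      expect_equal(got$start, oracle_scan(primer, s)$start, info = primer)
    }
  }
})

test_that("degenerate bases in the subject never satisfy a primer class", {
  # genome-side N is a literal, not a wildcard
  expect_equal(nrow(match_primer("AR", "ANAG")), 1)  # only AG at pos 2
  expect_equal(match_primer("AR", "ANAG")$start, 2)
})

test_that("find_amplicons pairs nearest downstream sites within max_insert", {
  set.seed(52)
  fwd <- primer_def("fp", "GGWCCATCGGATCA", "forward")
  rev <- primer_def("rp", "CCGTATGGCTTACG", "reverse")
  fwd_site <- "GGACCATCGGATCA"                   # expansion of the forward
  rev_site <- oracle_revcomp("CCGTATGGCTTACG")   # binding site on fwd strand
  spacer <- random_dna(200)
  genome <- paste0(random_dna(20), fwd_site, spacer, rev_site, random_dna(20))
  h <- find_amplicons(genome, fwd, rev, genome_id = "g")
  expect_equal(nrow(h), 1)
  expect_equal(h$fwd_start, 20)
  expect_equal(nchar(h$insert), 14 + 200 + 14)
  expect_equal(h$insert, substr(genome, 21, 20 + 228))

  # duplicated construct: two hits with copy_index 0, 1
  g2 <- paste0(genome, genome)
  h2 <- find_amplicons(g2, fwd, rev)
  expect_equal(h2$copy_index, c(0, 1))

  # distance bound
  far <- paste0(random_dna(20), fwd_site, random_dna(5000), rev_site)
  expect_equal(nrow(find_amplicons(far, fwd, rev, max_insert = 3000)), 0)
})

test_that("find_amplicons is strand-symmetric", {
  set.seed(53)
  fx <- generate_fixture_genomes(2, 2, divergence = 0.05)
  cf <- builtin_config("V4 PE 150 bp")
  for (gid in names(fx$genomes)) {
    g <- as.character(fx$genomes[[gid]])
    h_fwd <- find_amplicons(g, cf$forward, cf$reverse)
    h_rc <- find_amplicons(revcomp(g), cf$forward, cf$reverse)
    expect_equal(nrow(h_fwd), nrow(h_rc))
    expect_setequal(h_fwd$insert, h_rc$insert)
  }
})

test_that("fixture truth coordinates are recovered exactly", {
  set.seed(54)
  fx <- generate_fixture_genomes(3, 2, divergence = 0.08)
  pair <- full_length_pair()
  for (gid in names(fx$genomes)) {
    h <- find_amplicons(as.character(fx$genomes[[gid]]), pair$forward,
                        pair$reverse, genome_id = gid)
    tr <- fx$truth[fx$truth$genome_id == gid, ]
    expect_equal(nrow(h), nrow(tr))
    expect_equal(h$start, tr$start)
    expect_equal(h$end, tr$end)
  }
})

test_that("every concrete primer expansion matches at 0 and mutants do not", {
  # oracle-equivalence on a compact primer (full Table 1 covered in the
  # acceptance suite)
  primer <- "CYKAT"
  exps <- oracle_expansions(primer)
  expect_length(exps, 4)
  for (e in exps) {
    m <- match_primer(primer, e)
    expect_equal(m$start, 0)
    sets <- ORACLE_IUPAC[strsplit(primer, "")[[1]]]
    for (pos in seq_len(nchar(e))) {
      for (b in setdiff(c("A", "C", "G", "T"), sets[[pos]])) {
        mut <- e
        substr(mut, pos, pos) <- b
        expect_equal(nrow(match_primer(primer, mut)), 0)
      }
    }
  }
})

test_that("extract_reads respects layout geometry and length guards", {
  set.seed(55)
  insert <- random_dna(400)
  cfg_pe <- amp_config("toy PE 250", primer_def("f", "AAAA", "forward"),
                       primer_def("r", "TTTT", "reverse"), "PE", 250)
  rds <- extract_reads(insert, cfg_pe)
  expect_equal(rds$read1, substr(insert, 1, 250))
  expect_equal(rds$read2, revcomp(substr(insert, 151, 400)))
  # overlap consistency: revcomp(read2) is a suffix, read1 a prefix
  expect_equal(paste0(substr(rds$read1, 1, 150), revcomp(rds$read2)), insert)

  cfg_se <- amp_config("toy SE 150", primer_def("f", "AAAA", "forward"),
                       primer_def("r", "TTTT", "reverse"), "SE", 150)
  expect_null(extract_reads(random_dna(120), cfg_se))
  exact <- random_dna(150)
  expect_equal(extract_reads(exact, cfg_se)$read1, exact)
})

test_that("built-in tables load and configs resolve", {
  expect_equal(nrow(builtin_primers()), 13)
  expect_equal(nrow(builtin_configs()), 32)
  cf <- builtin_config("V4 PE 150 bp")
  expect_equal(cf$forward$name, "515F")
  expect_equal(cf$reverse$name, "806R")
  expect_equal(cf$layout, "PE")
  expect_error(builtin_config("V99 SE 1 bp"), "unknown configuration")
})
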