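test_that("exact substring reads align at identity 1.0", {
  g <- rand_seq(1000, seed = 42)
  db <- build_index(c(s1 = g), "donor")
  reads <- tiny_reads(c(substr(g, 101, 200), substr(g, 1, 100)))
  tab <- align(reads, db, min_identity = 1.0)
  expect_true(all(tab$aligned))
  expect_equal(tab$identity, c(1, 1))
  expect_equal(tab$scaffold_id, c("s1", "s1"))
})

test_that("one mismatch in 100 bp fails at 1.00 and passes at 0.98", {
  g <- rand_seq(1000, seed = 43)
  db <- build_index(c(s1 = g), "donor")
  r <- substr(g, 301, 400)
  substr(r, 50, 50) <- chartr("ACGT", "TGCA", substr(r, 50, 50))
  reads <- tiny_reads(r)
  expect_false(align(reads, db, 1.0)$aligned)
  tab98 <- align(reads, db, 0.98)
  expect_true(tab98$aligned)
  expect_equal(tab98$identity, 0.99)
})

test_that("reverse-complement reads align (strand symmetry)", {
  g <- rand_seq(1000, seed = 44)
  db <- build_index(c(s1 = g), "donor")
  reads <- tiny_reads(oracle_revcomp(substr(g, 201, 300)))
  expect_true(align(reads, db, 1.0)$aligned)
})

test_that("N-only reads are unaligned, not an error", {
  db <- build_index(c(s1 = rand_seq(500, seed = 45)), "donor")
  tab <- align(tiny_reads(strrep("N", 50)), db, 0.9)
  expect_false(tab$aligned)
  expect_true(is.na(tab$identity))
})

test_that("random reads do not align to an unrelated scaffold", {
  set.seed(46)
  g <- rand_seq(1000, seed = 47)
  db <- build_index(c(s1 = g), "donor")
  reads <- tiny_reads(vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    character(1)))
  tab <- align(reads, db, 0.98)
  expect_equal(sum(tab$aligned), 0L)
})

test_that("aligner agrees with the sliding-window brute-force oracle", {
  set.seed(48)
  g1 <- rand_seq(400, seed = 49)
  g2 <- rand_seq(400, seed = 50)
  scaffolds <- c(a = g1, b = g2)
  db <- build_index(scaffolds, "donor")
  # reads drawn from the scaffolds with 0-3 planted mismatches, both
  # strands, plus pure-random reads
  mk <- function(i) {
    src <- if (i %% 3 == 0) g2 else g1
    start <- sample.int(nchar(src) - 49L, 1L)
    r <- substr(src, start, start + 49L)
    nmm <- sample(0:3, 1)
    if (nmm > 0) {
      at <- sample.int(50, nmm)
      for (j in at) substr(r, j, j) <- chartr("ACGT", "GTAC", substr(r, j, j))
    }
    if (i %% 2 == 0) r <- oracle_revcomp(r)
    r
  }
  seqs <- c(vapply(1:30, mk, character(1)),
            vapply(1:5, function(i)
              paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                    collapse = ""), character(1)))
  reads <- tiny_reads(seqs)
  for (idn in c(1.0, 0.96, 0.9)) {
    got <- align(reads, db, idn)
    want <- oracle_align(reads, scaffolds, idn)
    expect_equal(got$aligned, want$aligned, info = paste("identity", idn))
    mm_got <- round((1 - got$identity) * 50)
    expect_equal(mm_got[got$aligned], want$mm[want$aligned],
                 info = paste("identity", idn))
  }
})

test_that("threshold monotonicity: stricter identity never gains reads", {
  ch <- generate_synthetic_cohort(genome_length = 5000L, depth = 400L,
                                  error_rate = 0.01, seed = 51)
  db <- build_index(c(ch$genomes$donor), "donor")
  t98 <- align(ch$donor, db, 0.98)
  t99 <- align(ch$donor, db, 0.99)
  t100 <- align(ch$donor, db, 1.0)
  expect_true(all(t100$aligned <= t99$aligned))
  expect_true(all(t99$aligned <= t98$aligned))
  # conservation: every queried read appears exactly once
  for (tab in list(t98, t99, t100)) {
    expect_equal(tab$total_reads_queried, 400L)
    expect_equal(sum(tab$aligned) + sum(!tab$aligned), 400L)
  }
})

test_that("error-free self-reads align to their own database at rate 1", {
  ch <- generate_synthetic_cohort(genome_length = 5000L, depth = 300L,
                                  seed = 52)
  db <- build_index(c(ch$genomes$donor), "donor")
  tab <- align(ch$donor, db, 1.0)
  expect_true(all(tab$aligned))
  expect_true(all(tab$identity == 1))
})

test_that("database invariants are enforced", {
  expect_error(build_index(c(a = "ACGT", a = "TTTT"), "donor"), "duplicate")
  expect_error(build_index(character(0), "donor"), "no scaffolds")
  expect_error(build_index(c("ACGT"), "donor"), "id")
})

test_that("fixture assembler passes scaffolds through; empty input errors", {
  scafs <- c(x = "ACGTACGTAA", y = "TTTTCCCCGG")
  rs <- tiny_reads("ACGTACGTAA")
  out <- assemble(rs, assembler_fixture(scafs))
  expect_equal(as.character(out), scafs)
  empty <- read_set("e", character(0), character(0))
  expect_error(assemble(empty, assembler_fixture(scafs)), "empty")
})

test_that("coverage assembler reconstructs >=90% of a genome tiled at 30x", {
  ch <- generate_synthetic_cohort(genome_length = 10000L, depth = 3000L,
                                  seed = 53)  # 3000*100/10000 = 30x
  scafs <- assemble(ch$donor, assembler_coverage(ch$genomes$donor))
  covered <- sum(Biostrings::width(scafs))
  expect_gte(covered / 10000, 0.9)
  # scaffolds are genuine substrings of the genome
  expect_true(all(vapply(as.character(scafs), grepl,
                         logical(1), x = ch$genomes$donor[[1]],
                         fixed = TRUE)))
})

test_that("coverage assembler output shrinks with read depth", {
  ch <- generate_synthetic_cohort(genome_length = 20000L, depth = 4000L,
                                  seed = 54)
  full <- assemble(ch$donor, assembler_coverage(ch$genomes$donor))
  shallow <- assemble(subsample_reads(ch$donor, 100L, seed = 1),
                      assembler_coverage(ch$genomes$donor))
  expect_lt(sum(Biostrings::width(shallow)), sum(Biostrings::width(full)))
})

test_that("external aligner backend agrees on exact-match reads", {
  ch <- generate_synthetic_cohort(genome_length = 5000L, depth = 500L,
                                  seed = 55)
  scafs <- c(ch$genomes$donor, ch$genomes$patient)
  db_naive <- build_index(scafs, "donor", backend_naive())
  db_ext <- build_index(scafs, "donor", backend_minimap2())
  reads <- ch$donor
  t_naive <- align(reads, db_naive, 1.0)
  t_ext <- align(reads, db_ext, 1.0)
  expect_equal(t_ext$aligned, t_naive$aligned)
  expect_true(all(t_naive$aligned))
})
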