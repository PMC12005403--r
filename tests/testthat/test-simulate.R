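test_that("subsampling is seeded, order-preserving and bounded", {
  rs <- tiny_reads(replicate(50, rand_seq(30, sample.int(1e6, 1))))
  full <- subsample_reads(rs, 50, seed = 3)
  expect_equal(full$read_id, rs$read_id)   # n = depth is the identity

  none <- subsample_reads(rs, 0, seed = 3)
  expect_equal(depth(none), 0L)

  a <- subsample_reads(rs, 20, seed = 4)
  b <- subsample_reads(rs, 20, seed = 4)
  expect_identical(a$read_id, b$read_id)   # determinism
  expect_true(all(diff(match(a$read_id, rs$read_id)) > 0))  # order kept

  expect_error(subsample_reads(rs, 51, seed = 1), "subsample")
})

test_that("mixture counts reproduce the published sampling arithmetic", {
  cts <- mixture_counts(8750000, 0.2)
  expect_equal(cts[["donor"]], 1750000)
  expect_equal(cts[["patient"]], 7000000)

  # identical ratios at reduced depth
  cts_small <- mixture_counts(8750, 0.2)
  expect_equal(cts_small[["donor"]], 1750)
  expect_equal(cts_small[["patient"]], 7000)

  # contaminated design: f = 0.5, c = 0.2 -> 20/40/40
  cc <- mixture_counts(1000, 0.5, 0.2)
  expect_equal(unname(cc), c(400, 400, 200))
})

test_that("mixtures carry exact composition by construction", {
  ch <- generate_synthetic_cohort(genome_length = 3000L, depth = 1200L,
                                  n_contaminant_genomes = 1L, seed = 31)
  mix <- make_mixture(ch$donor, ch$patient, 1000L, 0.3, seed = 5)
  expect_equal(sum(mix$reads$true_source == "donor"), 300L)
  expect_equal(sum(mix$reads$true_source == "patient"), 700L)
  expect_equal(mix$depth, 1000L)

  m0 <- make_mixture(ch$donor, ch$patient, 500L, 0, seed = 5)
  expect_true(all(m0$reads$true_source == "patient"))
  m1 <- make_mixture(ch$donor, ch$patient, 500L, 1, seed = 5)
  expect_true(all(m1$reads$true_source == "donor"))

  cmix <- make_contaminated_mixture(ch$donor, ch$patient, ch$contaminant,
                                    1000L, f = 0.5, c = 0.2, seed = 6)
  tab <- table(cmix$reads$true_source)
  expect_equal(tab[["contaminant"]], 200L)
  expect_equal(tab[["donor"]], 400L)
  expect_equal(tab[["patient"]], 400L)

  # c = 0 reduces to the plain mixture
  c0 <- make_contaminated_mixture(ch$donor, ch$patient, NULL, 600L,
                                  f = 0.4, c = 0, seed = 7)
  p0 <- make_mixture(ch$donor, ch$patient, 600L, 0.4, seed = 7)
  expect_identical(c0$reads$read_id, p0$reads$read_id)

  # boundary: f = 1 with contamination -> no patient reads
  b <- make_contaminated_mixture(ch$donor, ch$patient, ch$contaminant,
                                 500L, f = 1, c = 0.2, seed = 8)
  expect_equal(sum(b$reads$true_source == "patient"), 0L)

  expect_error(make_mixture(ch$donor, ch$patient, 5000L, 0.9, seed = 1),
               "too shallow")
})

test_that("cohort generation honours its determinism and sharing contracts", {
  a <- generate_synthetic_cohort(genome_length = 2000L, depth = 100L,
                                 seed = 41)
  b <- generate_synthetic_cohort(genome_length = 2000L, depth = 100L,
                                 seed = 41)
  expect_identical(a$donor$sequence, b$donor$sequence)
  expect_identical(a$genomes, b$genomes)

  full <- generate_synthetic_cohort(genome_length = 2000L, depth = 50L,
                                    shared_fraction = 1, seed = 42)
  expect_identical(unname(full$genomes$donor), unname(full$genomes$patient))

  # disjoint sources share no read-length sequence on either strand
  dis <- generate_synthetic_cohort(genome_length = 2000L, depth = 50L,
                                   seed = 43)
  shared <- magtrack:::.shared_kmers(dis$genomes$donor[[1]],
                                     dis$genomes$patient[[1]])
  expect_length(shared, 0)
})

test_that("the substitution error model hits its target rate", {
  ch <- generate_synthetic_cohort(genome_length = 5000L, depth = 10000L,
                                  error_rate = 0.01, read_length = 100L,
                                  seed = 44)
  # compare each read with the genome window it was drawn from
  g <- ch$genomes$donor[[1]]
  win <- substring(g, ch$donor$meta$pos, ch$donor$meta$pos + 99L)
  obs <- ch$donor$sequence
  obs[ch$donor$meta$minus] <- vapply(obs[ch$donor$meta$minus],
                                     oracle_revcomp, character(1),
                                     USE.NAMES = FALSE)
  mm <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
               obs, win, USE.NAMES = FALSE)
  rate <- mean(mm) / 100
  se <- sqrt(0.01 * 0.99 / (10000 * 100))
  expect_lt(abs(rate - 0.01), 4 * se)
  # mean per-read identity approximately 0.99
  expect_lt(abs(mean(1 - mm / 100) - 0.99), 0.001)
})

test_that("evaluation metrics follow their definitions", {
  ch <- generate_synthetic_cohort(genome_length = 3000L, depth = 600L,
                                  seed = 45)
  mix <- make_mixture(ch$donor, ch$patient, 400L, 0.5, seed = 9)
  dbs <- build_databases(ch$donor, ch$patient,
                         donor_assembler = assembler_coverage(ch$genomes$donor),
                         patient_assembler = assembler_coverage(ch$genomes$patient))
  est <- suppressWarnings(track_engraftment(mix$reads, dbs$donor_db,
                                            dbs$patient_db, dbs$profiles[[1]]))
  ev <- evaluate_engraftment(est, mix)
  expect_equal(ev$absolute_error, 0)
  expect_equal(ev$type2_rate, 0)
  expect_equal(ev$type1_rate, 0)   # no contaminant in the mixture

  # hand arithmetic: estimate 0.45 vs truth 0.50
  est2 <- est
  est2$proportions[["engrafted"]] <- 0.45
  expect_equal(evaluate_engraftment(est2, mix)$absolute_error, 0.05)
})

test_that("experiment design has one row per pair, fraction and identity", {
  d <- mixture_design(n_pairs = 15, fractions = seq(0, 1, by = 0.1),
                      identities = 1.0)
  expect_equal(nrow(d), 165L)
  expect_equal(length(unique(d$pair)), 15L)
  expect_equal(sum(d$pair == 1), 11L)

  d3 <- mixture_design(n_pairs = 2, identities = c(0.98, 0.99, 1.0))
  expect_equal(nrow(d3), 2 * 11 * 3)
})

test_that("a small mixture experiment recovers every fraction exactly", {
  ch <- generate_synthetic_cohort(genome_length = 10000L, depth = 3000L,
                                  seed = 46)
  tab <- suppressWarnings(run_mixture_experiment(ch, depth = 1000L, seed = 10))
  expect_equal(nrow(tab), 11L)
  expect_equal(tab$engrafted, tab$f)
  expect_true(all(tab$absolute_error < 1e-12))
  # monotone response across the series
  expect_true(all(diff(tab$engrafted) >= 0))
})

test_that("mixture experiments are reproducible for a fixed seed", {
  ch <- generate_synthetic_cohort(genome_length = 4000L, depth = 800L,
                                  error_rate = 0.005, seed = 47)
  t1 <- suppressWarnings(
    run_mixture_experiment(ch, depth = 400L, fractions = c(0.2, 0.8),
                           identities = 0.98, seed = 11))
  t2 <- suppressWarnings(
    run_mixture_experiment(ch, depth = 400L, fractions = c(0.2, 0.8),
                           identities = 0.98, seed = 11))
  expect_identical(t1, t2)
})
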