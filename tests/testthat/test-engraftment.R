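test_that("unmapped correction follows the stated arithmetic", {
  # equal mapped split, rates (0.02, 0.04), 1000 reads, 50 unmapped:
  # expected unmapped = 0.03 * 1000 = 30, novel = 20
  cls <- fake_classification(
    d = c(rep(TRUE, 400), rep(FALSE, 400), rep(TRUE, 150), rep(FALSE, 50)),
    p = c(rep(FALSE, 400), rep(TRUE, 400), rep(TRUE, 150), rep(FALSE, 50)))
  prof <- self_profile(0.5, 0.5, donor_self_unmapped_rate = 0.02,
                       patient_self_unmapped_rate = 0.04)
  alloc <- allocate_ambiguous(150, 0.5)   # keeps E = P
  corr <- correct_unmapped(cls, prof, alloc)
  expect_equal(corr$expected_unmapped_count, 30)
  expect_equal(corr$novel_count, 20)
  expect_false(corr$clamped)

  # perfect databases: every unmapped read is novel
  corr0 <- correct_unmapped(cls, self_profile(0.5, 0.5), alloc)
  expect_equal(corr0$novel_count, 50)

  # observed unmapped below expectation -> clamped at zero
  prof_hi <- self_profile(0.5, 0.5, 0.2, 0.2)
  corr_hi <- correct_unmapped(cls, prof_hi, alloc)
  expect_equal(corr_hi$novel_count, 0)
  expect_true(corr_hi$clamped)
})

test_that("proportions always sum to one and stay in [0, 1]", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:500, 1)
    cls <- fake_classification(d = sample(c(TRUE, FALSE), n, replace = TRUE),
                               p = sample(c(TRUE, FALSE), n, replace = TRUE))
    prof <- self_profile(runif(1), runif(1), runif(1, 0, 0.3),
                         runif(1, 0, 0.3))
    est <- suppressWarnings(engraftment_fit(cls, prof))
    expect_equal(sum(est$proportions), 1, tolerance = 1e-9)
    expect_true(all(est$proportions >= 0 & est$proportions <= 1))
  }
})

test_that("empty sample errors", {
  cls <- fake_classification(d = logical(0), p = logical(0))
  expect_error(suppressWarnings(engraftment_fit(cls, self_profile(0, 0))),
               "empty sample")
})

test_that("pure-source simulations hit the boundaries exactly", {
  ch <- generate_synthetic_cohort(genome_length = 5000L, depth = 500L,
                                  seed = 22)
  dbs <- build_databases(ch$donor, ch$patient,
                         donor_assembler = assembler_coverage(ch$genomes$donor),
                         patient_assembler = assembler_coverage(ch$genomes$patient))
  prof <- dbs$profiles[[1]]
  est1 <- suppressWarnings(track_engraftment(
    magtrack:::rs_subset(ch$donor, 1:300),
    dbs$donor_db, dbs$patient_db, prof))
  expect_equal(est1$proportions[["engrafted"]], 1)
  expect_equal(est1$proportions[["persistent"]], 0)
  expect_equal(est1$proportions[["novel"]], 0)

  est0 <- suppressWarnings(track_engraftment(
    magtrack:::rs_subset(ch$patient, 1:300),
    dbs$donor_db, dbs$patient_db, prof))
  expect_equal(est0$proportions[["engrafted"]], 0)
  expect_equal(est0$proportions[["persistent"]], 1)
})

test_that("a 50/50 disjoint error-free mixture is recovered exactly", {
  ch <- generate_synthetic_cohort(genome_length = 10000L, depth = 2000L,
                                  seed = 23)
  dbs <- build_databases(ch$donor, ch$patient,
                         donor_assembler = assembler_coverage(ch$genomes$donor),
                         patient_assembler = assembler_coverage(ch$genomes$patient))
  mix <- make_mixture(ch$donor, ch$patient, 1000L, 0.5, seed = 2)
  est <- suppressWarnings(track_engraftment(mix$reads, dbs$donor_db,
                                            dbs$patient_db, dbs$profiles[[1]]))
  expect_equal(est$proportions[["engrafted"]], 0.5)
  ev <- evaluate_engraftment(est, mix)
  expect_equal(ev$absolute_error, 0)
  expect_equal(ev$type2_rate, 0)
})

test_that("per-scaffold engrafted mass splits as the read assignments do", {
  # all engrafted reads on one scaffold
  cls <- fake_classification(d = rep(TRUE, 10), p = rep(FALSE, 10),
                             donor_scaffold = "only")
  alloc <- allocate_ambiguous(0, 0.5)
  pm <- per_mag_report(cls, alloc)
  expect_equal(pm, c(only = 10))

  # two scaffolds with equal unique-donor hits -> 50/50
  cls2 <- fake_classification(d = rep(TRUE, 10), p = rep(FALSE, 10),
                              donor_scaffold = rep(c("s1", "s2"), 5))
  pm2 <- per_mag_report(cls2, alloc)
  expect_equal(pm2[["s1"]], pm2[["s2"]])

  # ambiguous reads contribute at the posterior weight
  cls3 <- fake_classification(d = c(rep(TRUE, 4), rep(TRUE, 6)),
                              p = c(rep(FALSE, 4), rep(TRUE, 6)),
                              donor_scaffold = c(rep("u", 4), rep("a", 6)))
  alloc3 <- allocate_ambiguous(6, 0.25)
  pm3 <- per_mag_report(cls3, alloc3)
  expect_equal(pm3[["u"]], 4)
  expect_equal(pm3[["a"]], 6 * 0.25)
})

test_that("per-genome engrafted mass tracks a 3:1 donor abundance", {
  ch <- generate_synthetic_cohort(genome_length = 8000L, n_donor_genomes = 2L,
                                  depth = 2000L, donor_abundance = c(3, 1),
                                  seed = 24)
  dbs <- build_databases(ch$donor, ch$patient,
                         donor_assembler = assembler_coverage(ch$genomes$donor),
                         patient_assembler = assembler_coverage(ch$genomes$patient))
  post <- magtrack:::rs_subset(ch$donor, 1:1500)
  est <- suppressWarnings(track_engraftment(post, dbs$donor_db,
                                            dbs$patient_db, dbs$profiles[[1]]))
  mass <- tapply(est$per_mag, sub("_s\\d+$", "", names(est$per_mag)), sum)
  frac_g1 <- mass[["donor_g1"]] / sum(mass)
  truth <- mean(post$true_source == "donor" &
                  grepl("^donor_g1", post$meta$genome))
  expect_equal(frac_g1, truth)       # provenance oracle, error-free reads
  expect_lt(abs(frac_g1 - 0.75), 0.05)
})

test_that("estimate object methods expose the fit", {
  cls <- fake_classification(d = c(TRUE, TRUE, FALSE, TRUE),
                             p = c(FALSE, TRUE, TRUE, FALSE))
  est <- engraftment_fit(cls, self_profile(0.3, 0.2, 0.01, 0.01))
  expect_s3_class(est, "engraftment")
  co <- coef(est)
  expect_named(co, c("engrafted", "persistent", "novel"))
  expect_output(print(est), "engraftment")
  expect_output(print(summary(est)), "posterior")
})
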