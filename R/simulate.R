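# run code under a local, seeded RNG without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

.rand_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# all k-mers two sequences have in common (either strand of b)
.shared_kmers <- function(a, b, k = 31L) {
  if (nchar(a) < k || nchar(b) < k) return(character(0))
  ka <- substring(a, seq_len(nchar(a) - k + 1L), seq_len(nchar(a) - k + 1L) + k - 1L)
  rb <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  kb <- c(substring(b, seq_len(nchar(b) - k + 1L), seq_len(nchar(b) - k + 1L) + k - 1L),
          substring(rb, seq_len(nchar(rb) - k + 1L), seq_len(nchar(rb) - k + 1L) + k - 1L))
  intersect(ka, kb)
}

#' Generate a synthetic two-source (optionally three-source) cohort
#'
#' Desk-scale stand-in for a real donor / pre-treatment sample pair: random
#' source genomes with a controllable fraction of content shared verbatim
#' between donor and patient, reads sampled uniformly from both strands with
#' a per-base substitution error model, and full provenance labels. A
#' contaminant source (an unrelated community, optionally sharing content
#' with the donor) can be added for false-positive experiments.
#'
#' Genome construction copies the first `shared_fraction` of each donor
#' genome into the matching patient genome; contaminant genomes copy
#' `contaminant_shared_fraction` from the donor genome's tail, so the
#' donor-patient and donor-contaminant shared regions are disjoint. The
#' independently generated remainders are screened for chance shared 31-mers
#' (hence shared read-length matches) and resampled if any are found, so
#' `shared_fraction = 0` yields sources with no common read-length sequence.
#'
#' @param genome_length length of each source genome in bp (default 50000).
#' @param n_donor_genomes,n_patient_genomes,n_contaminant_genomes number of
#'   genomes per source (defaults 1, 1, 0).
#' @param shared_fraction fraction of donor genome content copied verbatim
#'   into the patient genome, in \[0, 1\].
#' @param contaminant_shared_fraction fraction of donor genome content
#'   copied into each contaminant genome; `shared_fraction +
#'   contaminant_shared_fraction` must not exceed 1.
#' @param read_length read length in bp (default 100).
#' @param error_rate per-base substitution probability (default 0).
#' @param depth reads per source sample (default 20000, the desk-scale
#'   analogue of a sequencing run).
#' @param donor_abundance optional relative read abundances over the donor
#'   genomes (e.g. `c(3, 1)`); defaults to uniform. Analogous weighting is
#'   applied to no other source.
#' @param seed integer seed; the cohort is a pure function of its arguments.
#' @return an object of class `synthetic_cohort`: read sets `donor`,
#'   `patient`, `contaminant` (NULL when absent), plus `genomes` (named list
#'   of per-source named genome vectors) and the generating parameters.
#' @export
generate_synthetic_cohort <- function(genome_length = 50000L,
                                      n_donor_genomes = 1L,
                                      n_patient_genomes = 1L,
                                      n_contaminant_genomes = 0L,
                                      shared_fraction = 0,
                                      contaminant_shared_fraction = 0,
                                      read_length = 100L,
                                      error_rate = 0,
                                      depth = 20000L,
                                      donor_abundance = NULL,
                                      seed = 1L) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            contaminant_shared_fraction >= 0,
            shared_fraction + contaminant_shared_fraction <= 1,
            read_length >= 20L, genome_length >= read_length,
            error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    L <- as.integer(genome_length)
    s_len <- as.integer(round(shared_fraction * L))
    c_len <- as.integer(round(contaminant_shared_fraction * L))
    donor_g <- stats::setNames(
      vapply(seq_len(n_donor_genomes), function(i) .rand_genome(L),
             character(1)),
      sprintf("donor_g%d", seq_len(n_donor_genomes)))
    make_partner <- function(template, prefix, n, shared_len, from_tail) {
      stats::setNames(vapply(seq_len(n), function(i) {
        tpl <- template[[((i - 1L) %% length(template)) + 1L]]
        shared <- if (shared_len > 0L) {
          if (from_tail) substr(tpl, L - shared_len + 1L, L)
          else substr(tpl, 1L, shared_len)
        } else ""
        for (try in 1:20) {
          rest <- if (L - shared_len > 0L) .rand_genome(L - shared_len) else ""
          # screen the free part against every donor genome for chance
          # read-length matches (a shared 100-mer implies a shared 31-mer)
          clash <- any(vapply(template, function(g)
            length(.shared_kmers(rest, g)) > 0, logical(1)))
          if (!clash) break
        }
        paste0(shared, rest)
      }, character(1)), sprintf("%s_g%d", prefix, seq_len(n)))
    }
    patient_g <- make_partner(donor_g, "patient", n_patient_genomes,
                              s_len, from_tail = FALSE)
    contam_g <- if (n_contaminant_genomes > 0L) {
      make_partner(donor_g, "contaminant", n_contaminant_genomes,
                   c_len, from_tail = TRUE)
    } else NULL
    # the patient free parts must not clash with each other's donors only;
    # also screen patient vs contaminant free parts via donor tails already
    sample_reads <- function(genomes, label, weights = NULL) {
      ng <- length(genomes)
      w <- if (is.null(weights)) rep(1, ng) else weights / sum(weights)
      gidx <- sample.int(ng, depth, replace = TRUE, prob = w)
      span <- nchar(genomes)[gidx] - read_length + 1L
      pos <- pmin(span, 1L + as.integer(floor(stats::runif(depth) * span)))
      seqs <- substring(genomes[gidx], pos, pos + read_length - 1L)
      minus <- sample(c(FALSE, TRUE), depth, replace = TRUE)
      if (any(minus)) {
        seqs[minus] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[minus])))
      }
      if (error_rate > 0) seqs <- .add_substitutions(seqs, error_rate)
      read_set(label, sprintf("%s_%06d", label, seq_len(depth)), seqs,
               true_source = if (label == "contaminant") "contaminant"
                             else label,
               meta = data.frame(genome = names(genomes)[gidx], pos = pos,
                                 minus = minus, stringsAsFactors = FALSE))
    }
    donor_rs <- sample_reads(donor_g, "donor", donor_abundance)
    patient_rs <- sample_reads(patient_g, "patient")
    contam_rs <- if (!is.null(contam_g)) sample_reads(contam_g, "contaminant")
                 else NULL
    structure(list(donor = donor_rs, patient = patient_rs,
                   contaminant = contam_rs,
                   genomes = list(donor = donor_g, patient = patient_g,
                                  contaminant = contam_g),
                   shared_fraction = shared_fraction,
                   contaminant_shared_fraction = contaminant_shared_fraction,
                   read_length = as.integer(read_length),
                   error_rate = error_rate, depth = as.integer(depth),
                   seed = as.integer(seed)),
              class = "synthetic_cohort")
  })
}

# vectorized per-base substitution errors (never to the original base)
.add_substitutions <- function(seqs, rate) {
  rl <- nchar(seqs)
  total <- sum(rl)
  hit <- which(stats::runif(total) < rate)
  if (!length(hit)) return(seqs)
  ends <- cumsum(rl)
  read_of <- findInterval(hit - 1L, ends) + 1L
  pos_in <- hit - c(0L, ends)[read_of]
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(hit)) {
    r <- read_of[i]; p <- pos_in[i]
    cur <- substr(seqs[r], p, p)
    sub <- sample(setdiff(bases, cur), 1L)
    substr(seqs[r], p, p) <- sub
  }
  seqs
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d bp genomes, shared %.0f%%, %d reads/source, error %.3f, seed %d\n",
    nchar(x$genomes$donor[[1L]]), 100 * x$shared_fraction, x$depth,
    x$error_rate, x$seed))
  invisible(x)
}

#' Subsample a read set without replacement
#'
#' Uniform, seeded, order-preserving sampling of `n` reads.
#'
#' @param reads a [read_set].
#' @param n number of reads to keep, `0 <= n <= depth(reads)`.
#' @param seed integer seed.
#' @return a [read_set] of depth `n`.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  stopifnot(inherits(reads, "read_set"), n >= 0)
  if (n > depth(reads))
    stop("cannot subsample ", n, " reads from a set of ", depth(reads))
  idx <- with_seed(seed, sort(sample.int(depth(reads), n)))
  rs_subset(reads, idx)
}

#' Read counts of a simulated mixture
#'
#' The bookkeeping behind [make_mixture()] and
#' [make_contaminated_mixture()]: `round(c * depth)` contaminant reads, and
#' the remaining `(1 - c)` of the depth split `f : (1 - f)` between donor
#' and patient with the donor count rounded to the nearest integer and the
#' remainder going to the patient source.
#'
#' @param depth total mixture depth in reads.
#' @param f donor fraction of the non-contaminant part, in \[0, 1\].
#' @param c contaminant fraction of the total, in \[0, 1).
#' @return named integer vector with `donor`, `patient`, `contaminant`
#'   summing to `depth`.
#' @export
mixture_counts <- function(depth, f, c = 0) {
  stopifnot(f >= 0, f <= 1, c >= 0, c < 1, depth >= 0)
  n_c <- round(c * depth)
  rest <- depth - n_c
  n_d <- round(f * rest)
  c(donor = n_d, patient = rest - n_d, contaminant = n_c)
}

#' Simulate a post-treatment sample at a fixed donor fraction
#'
#' Draws `round(f * depth)` reads from the donor sample and the remainder
#' from the patient (pre-treatment) sample, each by seeded subsampling, and
#' keeps the provenance labels — so the mixture's composition is exact by
#' construction and serves as ground truth.
#'
#' @param donor,patient source [read_set]s, deep enough for the draws.
#' @param depth total mixture depth.
#' @param f true donor fraction in \[0, 1\].
#' @param seed integer seed.
#' @param label sample label for the mixture.
#' @return an object of class `simulated_mixture`: a list with `reads` (a
#'   [read_set]), `true_donor_fraction`, `contaminant_fraction` and `depth`.
#' @export
make_mixture <- function(donor, patient, depth, f, seed = 1L,
                         label = sprintf("mix_f%02.0f", 100 * f)) {
  make_contaminated_mixture(donor, patient, contaminant = NULL,
                            depth = depth, f = f, c = 0, seed = seed,
                            label = label)
}

#' Simulate a contaminated post-treatment sample
#'
#' Injects a fraction `c` of reads from an unrelated contaminant source
#' while preserving the donor:patient ratio `f : (1 - f)` in the remainder
#' (e.g. `f = 0.5, c = 0.2` gives a 20/40/40
#' contaminant/donor/patient mixture).
#'
#' @inheritParams make_mixture
#' @param contaminant contaminant [read_set] (or NULL for `c = 0`).
#' @param c contaminant fraction of the total, in \[0, 1).
#' @return a `simulated_mixture` (see [make_mixture()]).
#' @export
make_contaminated_mixture <- function(donor, patient, contaminant, depth,
                                      f, c = 0.2, seed = 1L,
                                      label = sprintf("mix_f%02.0f_c%02.0f",
                                                      100 * f, 100 * c)) {
  cts <- mixture_counts(depth, f, c)
  if (cts[["donor"]] > depth(donor))
    stop("donor sample too shallow: need ", cts[["donor"]], " reads")
  if (cts[["patient"]] > depth(patient))
    stop("patient sample too shallow: need ", cts[["patient"]], " reads")
  parts <- list(subsample_reads(donor, cts[["donor"]], seed = seed),
                subsample_reads(patient, cts[["patient"]], seed = seed + 1L))
  if (cts[["contaminant"]] > 0L) {
    if (is.null(contaminant) || cts[["contaminant"]] > depth(contaminant))
      stop("contaminant sample too shallow: need ", cts[["contaminant"]],
           " reads")
    parts <- c(parts, list(subsample_reads(contaminant, cts[["contaminant"]],
                                           seed = seed + 2L)))
  }
  reads <- rs_concat(parts, label)
  structure(list(reads = reads, true_donor_fraction = f,
                 contaminant_fraction = c, depth = depth(reads)),
            class = "simulated_mixture")
}

#' @export
print.simulated_mixture <- function(x, ...) {
  cat(sprintf(
    "<simulated_mixture> '%s': %d reads, true donor fraction %.2f, contaminant %.2f\n",
    x$reads$sample_id, x$depth, x$true_donor_fraction,
    x$contaminant_fraction))
  invisible(x)
}

#' Evaluate an estimate against simulation ground truth
#'
#' * `absolute_error`: |estimated engrafted proportion - true donor share of
#'   the whole mixture| (for contaminated mixtures the truth is
#'   `f * (1 - c)`, e.g. 0.4 for a 50% donor mixture with 20% contaminant).
#' * `type2_rate` (false negatives): the fraction of donor-origin read mass
#'   not recovered as engrafted. Per-read engrafted mass counts uniquely
#'   donor-aligned reads fully and ambiguous reads at the posterior weight.
#' * `type1_rate` (false positives): the fraction of contaminant-origin
#'   read mass called engrafted; 0 when the mixture has no contaminant.
#'
#' @param estimate an `engraftment` estimate computed on `truth$reads`.
#' @param truth the `simulated_mixture` the estimate was computed on.
#' @return list with `absolute_error`, `type2_rate`, `type1_rate`.
#' @export
evaluate_engraftment <- function(estimate, truth) {
  stopifnot(inherits(estimate, "engraftment"),
            inherits(truth, "simulated_mixture"))
  pr <- estimate$counts$per_read
  m <- match(pr$read_id, truth$reads$read_id)
  if (anyNA(m)) stop("estimate and truth cover different reads")
  src <- truth$reads$true_source[m]
  post <- estimate$posterior_donor
  engrafted_mass <- function(sel) {
    sum(pr$d[sel] & !pr$p[sel]) + post * sum(pr$d[sel] & pr$p[sel])
  }
  true_share <- truth$true_donor_fraction * (1 - truth$contaminant_fraction)
  d_mass <- sum(src == "donor")
  c_mass <- sum(src == "contaminant")
  list(
    absolute_error = abs(estimate$proportions[["engrafted"]] - true_share),
    type2_rate = if (d_mass > 0)
      1 - engrafted_mass(src == "donor") / d_mass else 0,
    type1_rate = if (c_mass > 0)
      engrafted_mass(src == "contaminant") / c_mass else 0)
}

#' Design table for a mixture experiment
#'
#' One row per simulated sample: every pair crossed with every donor
#' fraction (the replication design — 15 pairs by fractions 0 to 1 in steps
#' of 0.1 — yields 165 samples) and, separately, each identity threshold is
#' evaluated on the same sample.
#'
#' @param n_pairs number of donor/pre-treatment pairs.
#' @param fractions donor fractions to simulate.
#' @param identities identity thresholds to evaluate.
#' @return data frame with columns `pair`, `f`, `identity`.
#' @export
mixture_design <- function(n_pairs = 15L, fractions = seq(0, 1, by = 0.1),
                           identities = 1.0) {
  expand.grid(pair = seq_len(n_pairs), f = fractions, identity = identities,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run a full mixture-series experiment
#'
#' For every cohort (donor/patient pair), donor fraction and identity
#' threshold: build the two databases with the coverage-limited simulated
#' assembler, estimate the self-alignment profile, simulate the mixture,
#' run the estimator, and record the estimate next to the truth. Databases
#' and profiles are built once per pair and identity and reused across the
#' fraction series.
#'
#' @param cohorts a `synthetic_cohort` or list of them (the pairs).
#' @param depth mixture depth in reads (default 20000).
#' @param fractions donor fractions (default 0 to 1 in steps of 0.1).
#' @param identities identity thresholds to evaluate (default 1.0).
#' @param seed integer seed for the mixture draws.
#' @return data frame: `pair`, `f`, `identity`, `engrafted`, `persistent`,
#'   `novel`, `posterior_donor`, `absolute_error`, `type2_rate`,
#'   `type1_rate`.
#' @export
run_mixture_experiment <- function(cohorts, depth = 20000L,
                                   fractions = seq(0, 1, by = 0.1),
                                   identities = 1.0, seed = 1L) {
  if (inherits(cohorts, "synthetic_cohort")) cohorts <- list(cohorts)
  rows <- list()
  for (pi in seq_along(cohorts)) {
    ch <- cohorts[[pi]]
    dbs <- build_databases(ch$donor, ch$patient,
                           donor_assembler = assembler_coverage(ch$genomes$donor),
                           patient_assembler = assembler_coverage(ch$genomes$patient),
                           min_identity = identities)
    for (idn in identities) {
      prof <- dbs$profiles[[as.character(idn)]]
      for (fi in seq_along(fractions)) {
        f <- fractions[fi]
        mix <- make_mixture(ch$donor, ch$patient, depth, f,
                            seed = seed + 1000L * pi + fi)
        est <- track_engraftment(mix$reads, dbs$donor_db, dbs$patient_db,
                                 prof, min_identity = idn)
        ev <- evaluate_engraftment(est, mix)
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pi, f = f, identity = idn,
          engrafted = est$proportions[["engrafted"]],
          persistent = est$proportions[["persistent"]],
          novel = est$proportions[["novel"]],
          posterior_donor = est$posterior_donor,
          absolute_error = ev$absolute_error,
          type2_rate = ev$type2_rate,
          type1_rate = ev$type1_rate)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run a depth-downsampling experiment
#'
#' Probes how sequencing depth affects the estimate. With
#' `side = "post_only"` the databases are built from the full-depth sources
#' and only the post-treatment mixture is drawn at each depth (the shallow
#' post-sequencing scenario); with `side = "sources_only"` the donor and
#' patient read sets are subsampled *before* assembly and profile
#' estimation while the post sample stays at `post_depth` (the shallow
#' source-sequencing scenario).
#'
#' @param cohort a `synthetic_cohort`.
#' @param depths depths to evaluate (reads).
#' @param side `"post_only"` or `"sources_only"`.
#' @param f true donor fraction of the post mixture (default 0.5).
#' @param post_depth post-sample depth for `sources_only` (default 5000).
#' @param min_identity identity threshold (default 1.0).
#' @param seed integer seed.
#' @return data frame: `side`, `depth`, `engrafted`, `absolute_error`.
#' @export
run_downsampling_experiment <- function(cohort, depths,
                                        side = c("post_only", "sources_only"),
                                        f = 0.5, post_depth = 5000L,
                                        min_identity = 1.0, seed = 1L) {
  side <- match.arg(side)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- list()
  if (side == "post_only") {
    dbs <- build_databases(cohort$donor, cohort$patient,
                           donor_assembler = assembler_coverage(cohort$genomes$donor),
                           patient_assembler = assembler_coverage(cohort$genomes$patient),
                           min_identity = min_identity)
    prof <- dbs$profiles[[as.character(min_identity)]]
    for (di in seq_along(depths)) {
      mix <- make_mixture(cohort$donor, cohort$patient, depths[di], f,
                          seed = seed + di)
      est <- track_engraftment(mix$reads, dbs$donor_db, dbs$patient_db,
                               prof, min_identity = min_identity)
      rows[[di]] <- data.frame(side = side, depth = depths[di],
                               engrafted = est$proportions[["engrafted"]],
                               absolute_error =
                                 evaluate_engraftment(est, mix)$absolute_error)
    }
  } else {
    for (di in seq_along(depths)) {
      d_sub <- subsample_reads(cohort$donor, depths[di], seed = seed + 10L * di)
      p_sub <- subsample_reads(cohort$patient, depths[di],
                               seed = seed + 10L * di + 1L)
      dbs <- build_databases(d_sub, p_sub,
                             donor_assembler = assembler_coverage(cohort$genomes$donor),
                             patient_assembler = assembler_coverage(cohort$genomes$patient),
                             min_identity = min_identity)
      prof <- dbs$profiles[[as.character(min_identity)]]
      mix <- make_mixture(cohort$donor, cohort$patient, post_depth, f,
                          seed = seed + di)
      est <- track_engraftment(mix$reads, dbs$donor_db, dbs$patient_db,
                               prof, min_identity = min_identity)
      rows[[di]] <- data.frame(side = side, depth = depths[di],
                               engrafted = est$proportions[["engrafted"]],
                               absolute_error =
                                 evaluate_engraftment(est, mix)$absolute_error)
    }
  }
  do.call(rbind, rows)
}
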