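#' Four-way classification of post-treatment reads
#'
#' Compares the alignment of one post-treatment sample against the donor
#' database and against the patient (pre-treatment) database and bins every
#' read: aligned only to the donor (`unique_donor`), only to the patient
#' (`unique_patient`), to both (`ambiguous`), or to neither (`unmapped`).
#' The four bins always partition the read set exactly.
#'
#' @param donor_table `alignment_table` of the sample vs the donor database.
#' @param patient_table `alignment_table` of the same reads vs the patient
#'   database; the two tables must cover an identical read-id set.
#' @param sample_id optional sample label for the result.
#' @return an object of class `classification` with elements `sample_id`,
#'   `n_total`, `counts` (named vector over the four bins) and `per_read`
#'   (data frame: `read_id`, alignment flags `d`/`p`, best donor and patient
#'   scaffold ids).
#' @export
classify_reads <- function(donor_table, patient_table, sample_id = "sample") {
  stopifnot(inherits(donor_table, "alignment_table"),
            inherits(patient_table, "alignment_table"))
  if (!setequal(donor_table$read_id, patient_table$read_id) ||
      donor_table$total_reads_queried != patient_table$total_reads_queried)
    stop("donor and patient alignment tables cover different read sets")
  m <- match(donor_table$read_id, patient_table$read_id)
  d <- donor_table$aligned
  p <- patient_table$aligned[m]
  per_read <- data.frame(
    read_id = donor_table$read_id,
    d = d, p = p,
    donor_scaffold = donor_table$scaffold_id,
    patient_scaffold = patient_table$scaffold_id[m],
    stringsAsFactors = FALSE)
  counts <- c(unique_donor = sum(d & !p),
              unique_patient = sum(!d & p),
              ambiguous = sum(d & p),
              unmapped = sum(!d & !p))
  structure(list(sample_id = sample_id,
                 n_total = length(d),
                 counts = counts,
                 per_read = per_read),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> sample '%s': %d reads\n", x$sample_id,
              x$n_total))
  print(x$counts)
  invisible(x)
}

#' Estimate the self/cross-alignment profile of the two sources
#'
#' Aligns each source sample's own reads against both databases. The
#' both-alignment rates are the empirical likelihoods of the Bayesian
#' reallocation: `donor_both_rate` estimates the probability that a
#' donor-origin read aligns to both databases (and `patient_both_rate` the
#' patient analogue), with denominator equal to all reads of that source.
#' The self-unmapped rates — the fraction of a source's reads failing to
#' align to its own database — quantify the read loss expected from
#' sequencing error and unassembled rare strains, and drive the novel-read
#' correction.
#'
#' @param donor_reads,patient_reads the source [read_set]s the databases
#'   were built from; must be non-empty.
#' @param donor_db,patient_db the corresponding `mag_db` objects.
#' @param min_identity identity threshold; use the same value as the
#'   post-sample classification.
#' @return an object of class `self_profile` with fields `donor_both_rate`,
#'   `patient_both_rate`, `donor_self_unmapped_rate`,
#'   `patient_self_unmapped_rate`.
#' @export
estimate_self_profile <- function(donor_reads, patient_reads,
                                  donor_db, patient_db,
                                  min_identity = 1.0) {
  stopifnot(inherits(donor_reads, "read_set"),
            inherits(patient_reads, "read_set"))
  if (depth(donor_reads) == 0L || depth(patient_reads) == 0L)
    stop("source read sets must be non-empty")
  d_on_d <- align(donor_reads, donor_db, min_identity)
  d_on_p <- align(donor_reads, patient_db, min_identity)
  p_on_d <- align(patient_reads, donor_db, min_identity)
  p_on_p <- align(patient_reads, patient_db, min_identity)
  both_rate <- function(self_tab, cross_tab) {
    m <- match(self_tab$read_id, cross_tab$read_id)
    mean(self_tab$aligned & cross_tab$aligned[m])
  }
  structure(list(
    donor_both_rate = both_rate(d_on_d, d_on_p),
    patient_both_rate = both_rate(p_on_p, p_on_d),
    donor_self_unmapped_rate = mean(!d_on_d$aligned),
    patient_self_unmapped_rate = mean(!p_on_p$aligned)),
    class = "self_profile")
}

#' Construct a self-alignment profile from known rates
#'
#' Mainly for tests and for replaying cached pipeline runs.
#'
#' @param donor_both_rate,patient_both_rate empirical both-database
#'   alignment rates (the Bayes likelihoods), in \[0, 1\].
#' @param donor_self_unmapped_rate,patient_self_unmapped_rate expected
#'   unmapped fractions of each source against its own database, in \[0, 1\].
#' @return a `self_profile`.
#' @export
self_profile <- function(donor_both_rate, patient_both_rate,
                         donor_self_unmapped_rate = 0,
                         patient_self_unmapped_rate = 0) {
  vals <- c(donor_both_rate, patient_both_rate,
            donor_self_unmapped_rate, patient_self_unmapped_rate)
  if (any(vals < 0 | vals > 1)) stop("profile rates must lie in [0, 1]")
  structure(list(donor_both_rate = donor_both_rate,
                 patient_both_rate = patient_both_rate,
                 donor_self_unmapped_rate = donor_self_unmapped_rate,
                 patient_self_unmapped_rate = patient_self_unmapped_rate),
            class = "self_profile")
}

#' @export
print.self_profile <- function(x, ...) {
  cat("<self_profile>\n")
  cat(sprintf("  P(both | donor origin):   %.4f\n", x$donor_both_rate))
  cat(sprintf("  P(both | patient origin): %.4f\n", x$patient_both_rate))
  cat(sprintf("  self-unmapped (donor):    %.4f\n",
              x$donor_self_unmapped_rate))
  cat(sprintf("  self-unmapped (patient):  %.4f\n",
              x$patient_self_unmapped_rate))
  invisible(x)
}
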