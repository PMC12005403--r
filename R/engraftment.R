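#' Correct the unmapped bin for expected read loss
#'
#' Unmapped post-treatment reads have three causes: sequencing errors,
#' source content missing from the assembled databases, and genuinely novel
#' strains (diet/environment). The first two are estimated from the
#' self-alignment profile: each source's self-unmapped rate is applied to
#' the mapped-mass split between the sources, giving the expected number of
#' unmapped reads attributable to error and missing assembly; whatever
#' remains of the observed unmapped bin is attributed to novel strains
#' (clamped at zero — a deficit cannot be negative).
#'
#' @param classification a `classification`.
#' @param profile a `self_profile`.
#' @param alloc a `posterior_allocation` for the ambiguous bin.
#' @return list with `novel_count`, `expected_unmapped_count`, the applied
#'   unmapped rate `u`, and `clamped` (TRUE when the observed unmapped bin
#'   fell below expectation).
#' @export
correct_unmapped <- function(classification, profile, alloc) {
  stopifnot(inherits(classification, "classification"),
            inherits(profile, "self_profile"),
            inherits(alloc, "posterior_allocation"))
  cts <- classification$counts
  E <- cts[["unique_donor"]] + alloc$ambiguous_to_donor
  P <- cts[["unique_patient"]] + alloc$ambiguous_to_patient
  if (E + P == 0) {
    warning("no mapped mass; using the mean of the self-unmapped rates")
    u <- mean(c(profile$donor_self_unmapped_rate,
                profile$patient_self_unmapped_rate))
  } else {
    u <- (E * profile$donor_self_unmapped_rate +
          P * profile$patient_self_unmapped_rate) / (E + P)
  }
  expected <- u * classification$n_total
  novel <- max(0, cts[["unmapped"]] - expected)
  list(novel_count = novel, expected_unmapped_count = expected, u = u,
       clamped = cts[["unmapped"]] < expected)
}

#' Combine classification, allocation and correction into the estimate
#'
#' Produces the final community proportions. The engrafted mass is the
#' uniquely donor-aligned reads plus the donor share of the ambiguous bin
#' plus the donor share of the expected-unmapped mass; persistent mass is
#' the patient analogue; novel mass is the corrected unmapped remainder.
#' The expected-unmapped mass is redistributed to donor/patient in
#' proportion to the mapped-mass split, since reads lost to error or
#' missing assembly arise from whichever source contributed them. The three
#' proportions sum to 1 up to the clamping of the novel bin (when the
#' observed unmapped bin falls below expectation, the surplus expectation is
#' truncated so the total still normalises).
#'
#' @inheritParams correct_unmapped
#' @param correction result of [correct_unmapped()].
#' @return an object of class `engraftment`; see [track_engraftment()].
#' @export
summarize_engraftment <- function(classification, alloc, correction,
                                  profile = NULL) {
  stopifnot(inherits(classification, "classification"),
            inherits(alloc, "posterior_allocation"))
  n <- classification$n_total
  if (n == 0L) stop("empty sample: no reads to summarise")
  cts <- classification$counts
  E <- cts[["unique_donor"]] + alloc$ambiguous_to_donor
  P <- cts[["unique_patient"]] + alloc$ambiguous_to_patient
  # redistribute only the unmapped mass actually available after clamping
  redistributable <- cts[["unmapped"]] - correction$novel_count
  if (E + P > 0) {
    r_d <- E / (E + P)
  } else {
    r_d <- 0.5
  }
  engrafted <- (E + r_d * redistributable) / n
  persistent <- (P + (1 - r_d) * redistributable) / n
  novel <- correction$novel_count / n
  structure(list(
    sample_id = classification$sample_id,
    proportions = c(engrafted = engrafted, persistent = persistent,
                    novel = novel),
    posterior_donor = alloc$posterior_donor,
    counts = classification,
    allocation = alloc,
    correction = correction,
    profile = profile,
    per_mag = per_mag_report(classification, alloc)),
    class = "engraftment")
}

#' Per-scaffold engrafted read mass
#'
#' For each donor scaffold: the number of uniquely donor-aligned reads whose
#' best donor hit is that scaffold, plus the posterior-weighted count of
#' ambiguous reads best-hitting it. Normalising the result gives the
#' percentage of engrafted reads per scaffold — the entry point for
#' downstream binning and taxonomic profiling of engrafted material.
#'
#' @param classification a `classification` with a populated per-read map.
#' @param alloc a `posterior_allocation`.
#' @return named numeric vector: scaffold id -> engrafted read mass.
#' @export
per_mag_report <- function(classification, alloc) {
  pr <- classification$per_read
  post <- alloc$posterior_donor
  uniq <- pr$d & !pr$p
  amb <- pr$d & pr$p
  scafs <- unique(c(pr$donor_scaffold[uniq], pr$donor_scaffold[amb]))
  scafs <- scafs[!is.na(scafs)]
  out <- stats::setNames(numeric(length(scafs)), scafs)
  if (any(uniq)) {
    t1 <- table(pr$donor_scaffold[uniq])
    out[names(t1)] <- out[names(t1)] + as.numeric(t1)
  }
  if (any(amb) && post > 0) {
    t2 <- table(pr$donor_scaffold[amb])
    out[names(t2)] <- out[names(t2)] + post * as.numeric(t2)
  }
  out
}

#' Track engraftment of one post-treatment sample
#'
#' The per-sample estimator: aligns the post-treatment reads against the
#' donor and patient databases, bins them four ways, estimates priors from
#' the uniquely assigned reads, resolves the ambiguous bin with the Bayes
#' posterior, corrects the unmapped bin for expected read loss, and returns
#' the engrafted/persistent/novel decomposition.
#'
#' @param post a [read_set] of post-treatment reads (non-empty).
#' @param donor_db,patient_db `mag_db` objects for the two sources.
#' @param profile a `self_profile` for the same databases and threshold,
#'   from [estimate_self_profile()].
#' @param min_identity alignment identity threshold in (0, 1]; the default
#'   1.0 minimises false-positive engraftment calls, 0.98 trades some of
#'   that stringency for lower false-negative rates.
#' @return an object of class `engraftment` with components `proportions`
#'   (named vector: engrafted, persistent, novel), `posterior_donor`,
#'   `counts` (the four-way `classification`), `allocation`, `correction`,
#'   `profile` and `per_mag`. Methods: `print`, `summary`, `coef`.
#' @export
track_engraftment <- function(post, donor_db, patient_db, profile,
                              min_identity = 1.0) {
  stopifnot(inherits(post, "read_set"))
  if (depth(post) == 0L) stop("empty sample: no post-treatment reads")
  tab_d <- align(post, donor_db, min_identity)
  tab_p <- align(post, patient_db, min_identity)
  cls <- classify_reads(tab_d, tab_p, sample_id = post$sample_id)
  engraftment_fit(cls, profile)
}

#' Fit the engraftment estimate from a classification and a profile
#'
#' The estimator applied to an existing four-way classification: priors ->
#' posterior -> ambiguous allocation -> unmapped correction -> proportions.
#'
#' @param classification a `classification`.
#' @param profile a `self_profile`.
#' @return an `engraftment` object (see [track_engraftment()]).
#' @export
engraftment_fit <- function(classification, profile) {
  priors <- estimate_priors(classification)
  post <- posterior_donor(priors, profile)
  alloc <- allocate_ambiguous(classification$counts[["ambiguous"]], post)
  corr <- correct_unmapped(classification, profile, alloc)
  summarize_engraftment(classification, alloc, corr, profile = profile)
}

#' @export
print.engraftment <- function(x, digits = 4, ...) {
  cat(sprintf("<engraftment> sample '%s' (%d reads)\n", x$sample_id,
              x$counts$n_total))
  print(round(x$proportions, digits))
  invisible(x)
}

#' @method summary engraftment
#' @export
summary.engraftment <- function(object, ...) {
  structure(object, class = c("summary.engraftment", "engraftment"))
}

#' @export
print.summary.engraftment <- function(x, digits = 4, ...) {
  cat(sprintf("Engraftment estimate for sample '%s'\n", x$sample_id))
  cat(sprintf("  reads: %d total | %d unique donor, %d unique patient, %d ambiguous, %d unmapped\n",
              x$counts$n_total,
              x$counts$counts[["unique_donor"]],
              x$counts$counts[["unique_patient"]],
              x$counts$counts[["ambiguous"]],
              x$counts$counts[["unmapped"]]))
  cat(sprintf("  ambiguous-read posterior (donor): %.4f\n",
              x$posterior_donor))
  cat(sprintf("  expected unmapped: %.1f (novel: %.1f%s)\n",
              x$correction$expected_unmapped_count,
              x$correction$novel_count,
              if (x$correction$clamped) ", clamped at 0" else ""))
  cat("  proportions:\n")
  print(round(x$proportions, digits))
  if (length(x$per_mag)) {
    top <- sort(x$per_mag, decreasing = TRUE)
    top <- utils::head(top, 5L)
    cat("  top engrafted scaffolds:\n")
    for (i in seq_along(top))
      cat(sprintf("    %s: %.1f reads\n", names(top)[i], top[i]))
  }
  invisible(x)
}

#' @importFrom stats coef
#' @method coef engraftment
#' @export
coef.engraftment <- function(object, ...) object$proportions
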