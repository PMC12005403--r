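#' Estimate source priors from uniquely assigned reads
#'
#' The prior probability that an ambiguous read originates from the donor is
#' taken as the proportion of the sample's uniquely assigned reads that were
#' uniquely donor-aligned: `n_unique_donor / (n_unique_donor +
#' n_unique_patient)`. Reads that are themselves ambiguous or unmapped carry
#' no unique source information and are excluded from the denominator. When
#' no read is uniquely assigned to either source the prior falls back to an
#' uninformative (0.5, 0.5) with a warning.
#'
#' @param classification a `classification` from [classify_reads()].
#' @return an object of class `source_priors` with `prior_donor` and
#'   `prior_patient` summing to 1.
#' @export
estimate_priors <- function(classification) {
  stopifnot(inherits(classification, "classification"))
  nd <- classification$counts[["unique_donor"]]
  np <- classification$counts[["unique_patient"]]
  if (nd + np == 0) {
    warning("no uniquely assigned reads; falling back to uniform priors")
    pd <- 0.5
  } else {
    pd <- nd / (nd + np)
  }
  structure(list(prior_donor = pd, prior_patient = 1 - pd),
            class = "source_priors")
}

#' @export
print.source_priors <- function(x, ...) {
  cat(sprintf("<source_priors> donor %.4f / patient %.4f\n",
              x$prior_donor, x$prior_patient))
  invisible(x)
}

#' Posterior probability that an ambiguous read is donor-derived
#'
#' Bayes' theorem over the hidden source indicator z of an ambiguous read,
#' conditioned on the observation that the read aligned to both databases:
#'
#'   P(z | p, d) = L_d pi_d / (L_d pi_d + L_p pi_p)
#'
#' where the likelihoods L_d = P(both | donor origin) and
#' L_p = P(both | patient origin) are the empirical both-alignment rates of
#' the self-alignment profile and pi are the unique-read priors. All
#' ambiguous reads of a sample share the same observation (aligned to both),
#' so the posterior is a single scalar per sample. When both likelihoods are
#' zero the observation carries no information and the prior is returned
#' with a warning.
#'
#' @param priors a `source_priors`.
#' @param profile a `self_profile`.
#' @return posterior probability in \[0, 1\].
#' @export
posterior_donor <- function(priors, profile) {
  stopifnot(inherits(priors, "source_priors"),
            inherits(profile, "self_profile"))
  if (profile$donor_both_rate == profile$patient_both_rate) {
    # equal likelihoods carry no information; return the prior exactly
    # (also covers the zero-denominator case)
    if (profile$donor_both_rate == 0)
      warning("both likelihoods are zero; returning the prior")
    return(priors$prior_donor)
  }
  num <- profile$donor_both_rate * priors$prior_donor
  den <- num + profile$patient_both_rate * priors$prior_patient
  if (den == 0) {
    warning("both likelihoods are zero; returning the prior")
    return(priors$prior_donor)
  }
  num / den
}

#' Allocate ambiguous reads between donor and patient
#'
#' Deterministic fractional (expected-count) allocation: all ambiguous reads
#' share one posterior, so the expected donor share is `n * posterior`. Mass
#' is conserved exactly.
#'
#' @param n_ambiguous number of ambiguous reads (>= 0).
#' @param posterior scalar posterior from [posterior_donor()].
#' @return an object of class `posterior_allocation` with fields
#'   `posterior_donor`, `ambiguous_to_donor`, `ambiguous_to_patient`.
#' @export
allocate_ambiguous <- function(n_ambiguous, posterior) {
  stopifnot(n_ambiguous >= 0, posterior >= 0, posterior <= 1)
  to_d <- n_ambiguous * posterior
  structure(list(posterior_donor = posterior,
                 ambiguous_to_donor = to_d,
                 ambiguous_to_patient = n_ambiguous - to_d),
            class = "posterior_allocation")
}

#' @export
print.posterior_allocation <- function(x, ...) {
  cat(sprintf(
    "<posterior_allocation> posterior %.4f: %.1f to donor, %.1f to patient\n",
    x$posterior_donor, x$ambiguous_to_donor, x$ambiguous_to_patient))
  invisible(x)
}
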