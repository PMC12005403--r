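# Independent brute-force alignment oracle: slides a read over every
# position of every scaffold on both strands and counts mismatches
# directly on character vectors. Deliberately naive (O(n * L * G)); used
# only at tiny scale to cross-check the package aligner.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# best placement of one read: list(mm, scaffold) or NULL if nothing within
# the mismatch budget
oracle_best_hit <- function(read, scaffolds, max_mm) {
  L <- nchar(read)
  best <- NULL
  rchars <- list(strsplit(read, "")[[1]], strsplit(oracle_revcomp(read), "")[[1]])
  for (si in seq_along(scaffolds)) {
    schars <- strsplit(scaffolds[[si]], "")[[1]]
    G <- length(schars)
    if (G < L) next
    for (strand in 1:2) {
      rc <- rchars[[strand]]
      for (start in seq_len(G - L + 1L)) {
        window <- schars[start:(start + L - 1L)]
        mm <- sum(rc != window | rc == "N")
        if (mm <= max_mm && (is.null(best) || mm < best$mm))
          best <- list(mm = mm, scaffold = si)
      }
    }
  }
  best
}

oracle_align <- function(rs, scaffolds, min_identity) {
  L <- nchar(rs$sequence)
  max_mm <- floor((1 - min_identity) * L + 1e-9)
  hits <- lapply(seq_along(rs$sequence), function(i)
    oracle_best_hit(rs$sequence[i], scaffolds, max_mm[i]))
  data.frame(
    read_id = rs$read_id,
    aligned = !vapply(hits, is.null, logical(1)),
    mm = vapply(hits, function(h) if (is.null(h)) NA_integer_ else h$mm,
                integer(1)))
}

# tiny deterministic helpers used across test files
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_reads <- function(seqs, prefix = "r", sample_id = "s") {
  read_set(sample_id, paste0(prefix, seq_along(seqs)), seqs)
}

# classification built directly from flag vectors, bypassing alignment
fake_classification <- function(d, p, sample_id = "s",
                                donor_scaffold = NULL) {
  n <- length(d)
  ids <- sprintf("r%03d", seq_len(n))
  tab_d <- magtrack:::.new_alignment_table(
    "donor", ids, d, ifelse(d, 1, NA_real_),
    if (is.null(donor_scaffold)) ifelse(d, "ds", NA_character_)
    else ifelse(d, donor_scaffold, NA_character_))
  tab_p <- magtrack:::.new_alignment_table(
    "patient", ids, p, ifelse(p, 1, NA_real_),
    ifelse(p, "ps", NA_character_))
  classify_reads(tab_d, tab_p, sample_id = sample_id)
}
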