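#' Construct a read set
#'
#' A `read_set` is the in-memory container for one sample's shotgun reads:
#' parallel vectors of identifiers, sequences, optional per-base qualities,
#' mate annotation and (for simulated reads) true source provenance. It is the
#' unit the classifier, the simulator and the aligner backends all operate on.
#'
#' @param sample_id single string naming the sample.
#' @param read_id character vector of unique read identifiers.
#' @param sequence character vector of nucleotide sequences over `A,C,G,T,N`.
#' @param quality optional character vector of per-base quality strings, same
#'   lengths as `sequence`, or `NULL`.
#' @param mate one of `"r1"`, `"r2"`, `"unpaired"`, recycled to all reads.
#' @param true_source per-read provenance label: `"donor"`, `"patient"`,
#'   `"contaminant"` or `"unknown"` (real data). Recycled.
#' @param meta optional data frame of per-read simulation metadata (genome of
#'   origin, 1-based start position, strand); used by the coverage-limited
#'   simulated assembler and by the evaluation oracles.
#' @return an object of class `read_set`.
#' @export
read_set <- function(sample_id, read_id, sequence, quality = NULL,
                     mate = "unpaired", true_source = "unknown", meta = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  read_id <- as.character(read_id)
  sequence <- toupper(as.character(sequence))
  n <- length(read_id)
  if (length(sequence) != n)
    stop("read_id and sequence must have equal length")
  if (n > 0L && any(!nzchar(sequence)))
    stop("read sequences must have length >= 1")
  if (anyDuplicated(read_id))
    stop("read identifiers must be unique within a read_set")
  if (!is.null(quality)) {
    quality <- as.character(quality)
    if (length(quality) != n || any(nchar(quality) != nchar(sequence)))
      stop("quality strings must match sequence lengths")
  }
  mate <- rep_len(match.arg(mate, c("r1", "r2", "unpaired")), n)
  true_source <- rep_len(true_source, n)
  bad <- setdiff(unique(true_source),
                 c("donor", "patient", "contaminant", "unknown"))
  if (length(bad))
    stop("unknown true_source label(s): ", paste(bad, collapse = ", "))
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != n) stop("meta must have one row per read")
  }
  structure(
    list(sample_id = sample_id, read_id = read_id, sequence = sequence,
         quality = quality, mate = mate, true_source = true_source,
         meta = meta),
    class = "read_set")
}

#' Number of reads in a read set
#' @param x a `read_set`.
#' @return integer read count.
#' @export
depth <- function(x) {
  stopifnot(inherits(x, "read_set"))
  length(x$read_id)
}

#' @export
print.read_set <- function(x, ...) {
  src <- table(x$true_source)
  cat(sprintf("<read_set> sample '%s': %d reads\n", x$sample_id, depth(x)))
  if (!identical(names(src), "unknown"))
    cat("  provenance:", paste(sprintf("%s=%d", names(src), src),
                               collapse = ", "), "\n")
  invisible(x)
}

# positional subset, order preserving
rs_subset <- function(rs, idx) {
  read_set(rs$sample_id, rs$read_id[idx], rs$sequence[idx],
           quality = if (is.null(rs$quality)) NULL else rs$quality[idx],
           true_source = rs$true_source[idx],
           meta = if (is.null(rs$meta)) NULL else rs$meta[idx, , drop = FALSE])
}

# concatenate read sets; ids must stay unique
rs_concat <- function(sets, sample_id) {
  read_set(sample_id,
           unlist(lapply(sets, `[[`, "read_id"), use.names = FALSE),
           unlist(lapply(sets, `[[`, "sequence"), use.names = FALSE),
           quality = if (all(vapply(sets, function(s) !is.null(s$quality),
                                    logical(1)))) {
             unlist(lapply(sets, `[[`, "quality"), use.names = FALSE)
           } else NULL,
           true_source = unlist(lapply(sets, `[[`, "true_source"),
                                use.names = FALSE),
           meta = if (all(vapply(sets, function(s) !is.null(s$meta),
                                 logical(1)))) {
             do.call(rbind, lapply(sets, `[[`, "meta"))
           } else NULL)
}

#' Read FASTQ files into a single read set
#'
#' Multiple files are concatenated in list order into one sample — the
#' supported way to pool several donor preparations (or several baseline
#' samples) into a single source. Gzipped input is detected from the file
#' content, not the extension. Reads keep file order; identifiers are the
#' FASTQ header up to the first whitespace. When the same identifier occurs
#' more than once (e.g. the two mates of a pair read from separate files),
#' an occurrence suffix `"/k"` is appended to keep identifiers unique.
#'
#' @param paths character vector of FASTQ (optionally gzipped) file paths.
#' @param sample_id sample name for the resulting set; defaults to the
#'   basename of the first file.
#' @return a [read_set].
#' @export
read_fastq <- function(paths, sample_id = NULL) {
  stopifnot(length(paths) >= 1L)
  if (!all(file.exists(paths)))
    stop("missing FASTQ file(s): ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  if (is.null(sample_id))
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths[[1L]]))
  ids <- character(0); seqs <- character(0); quals <- character(0)
  for (p in paths) {
    x <- .parse_fastq(p)
    ids <- c(ids, x$id)
    seqs <- c(seqs, x$seq)
    quals <- c(quals, x$qual)
  }
  if (anyDuplicated(ids)) {
    occ <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    dup <- ids %in% ids[duplicated(ids)]
    ids[dup] <- paste0(ids[dup], "/", occ[dup])
  }
  names(seqs) <- NULL
  read_set(sample_id, ids, seqs, quality = if (length(quals)) quals else NULL)
}

# validating 4-line FASTQ reader; file() transparently decompresses gzip
# (magic-byte detection, not extension)
.parse_fastq <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  bad <- function(rec, why)
    stop(sprintf("malformed FASTQ in '%s' at record %d (%s)", path, rec, why),
         call. = FALSE)
  if (length(lines) %% 4L != 0L)
    bad(length(lines) %/% 4L + 1L, "truncated 4-line block")
  if (!length(lines))
    return(list(id = character(0), seq = character(0), qual = character(0)))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (any(!startsWith(hdr, "@"))) bad(which(!startsWith(hdr, "@"))[1L],
                                      "header does not start with '@'")
  if (any(!startsWith(plus, "+"))) bad(which(!startsWith(plus, "+"))[1L],
                                       "separator does not start with '+'")
  if (any(nchar(qual) != nchar(seq)))
    bad(which(nchar(qual) != nchar(seq))[1L],
        "quality length differs from sequence length")
  list(id = sub("\\s.*$", "", substring(hdr, 2L)), seq = seq, qual = qual)
}

#' Write a read set as FASTQ
#'
#' Qualities default to a constant placeholder (`I`) when the set carries
#' none, e.g. for simulated reads. A `.gz` suffix triggers gzip output.
#'
#' @param rs a [read_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  qual <- rs$quality
  if (is.null(qual)) qual <- strrep("I", nchar(rs$sequence))
  lines <- as.vector(rbind(paste0("@", rs$read_id), rs$sequence, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write the per-sample engraftment report
#'
#' One TSV row per sample: the three community proportions (engrafted,
#' persistent, novel), the ambiguous-read posterior, and the four-way read
#' counts. Proportions are serialized to 9 decimal places.
#'
#' @param estimate an [engraftment] estimate.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(estimate, path) {
  stopifnot(inherits(estimate, "engraftment"))
  cts <- estimate$counts
  df <- data.frame(
    sample_id = estimate$sample_id,
    engrafted = sprintf("%.9f", estimate$proportions[["engrafted"]]),
    persistent = sprintf("%.9f", estimate$proportions[["persistent"]]),
    novel = sprintf("%.9f", estimate$proportions[["novel"]]),
    posterior_donor = sprintf("%.9f", estimate$posterior_donor),
    n_unique_donor = cts$counts[["unique_donor"]],
    n_unique_patient = cts$counts[["unique_patient"]],
    n_ambiguous = cts$counts[["ambiguous"]],
    n_unmapped = cts$counts[["unmapped"]],
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an engraftment report TSV back into a data frame
#' @param path report path written by [write_report].
#' @return data frame with numeric proportion columns.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write the engrafted-reads table
#'
#' Lists every read attributed to the donor together with its best-hit donor
#' scaffold, so engrafted material can be handed to downstream binning or
#' taxonomy tools. Uniquely donor-aligned reads carry call `unique_donor` and
#' posterior 1; ambiguous reads are listed (call `ambiguous_donor`) only when
#' the sample posterior exceeds 0.5 (ties go to the patient).
#'
#' @param estimate an [engraftment] estimate.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_engrafted_reads <- function(estimate, path) {
  stopifnot(inherits(estimate, "engraftment"))
  pr <- estimate$counts$per_read
  post <- estimate$posterior_donor
  uniq <- pr$d & !pr$p
  amb <- pr$d & pr$p & post > 0.5
  df <- data.frame(
    read_id = c(pr$read_id[uniq], pr$read_id[amb]),
    scaffold_id = c(pr$donor_scaffold[uniq], pr$donor_scaffold[amb]),
    call = c(rep("unique_donor", sum(uniq)), rep("ambiguous_donor", sum(amb))),
    posterior_donor = c(rep(1, sum(uniq)), rep(post, sum(amb))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-scaffold engrafted mass table
#' @param estimate an [engraftment] estimate.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_per_mag <- function(estimate, path) {
  stopifnot(inherits(estimate, "engraftment"))
  pm <- estimate$per_mag
  total <- sum(pm)
  df <- data.frame(
    scaffold_id = names(pm),
    engrafted_count = as.numeric(pm),
    engrafted_percent = if (total > 0) 100 * as.numeric(pm) / total else 0,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study manifest
#'
#' The manifest is a flat YAML file wiring one patient's samples together:
#' `patient_id`, `donor_fastqs` (one or more files, concatenated),
#' `baseline_fastqs` (one or more), `post_samples` (mapping of label to
#' FASTQ path(s)), optional `min_identity` (default 1.0) and `seed`.
#'
#' @param path YAML manifest path.
#' @return an object of class `study_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  m <- yaml::read_yaml(path)
  for (f in c("patient_id", "donor_fastqs", "baseline_fastqs", "post_samples"))
    if (is.null(m[[f]])) stop("manifest is missing required field '", f, "'")
  m$donor_fastqs <- as.character(unlist(m$donor_fastqs))
  m$baseline_fastqs <- as.character(unlist(m$baseline_fastqs))
  m$post_samples <- lapply(m$post_samples, function(p) as.character(unlist(p)))
  if (is.null(m$min_identity)) m$min_identity <- 1.0
  if (m$min_identity <= 0 || m$min_identity > 1)
    stop("min_identity must be in (0, 1]")
  if (is.null(m$seed)) m$seed <- 1L
  all_paths <- c(m$donor_fastqs, m$baseline_fastqs,
                 unlist(m$post_samples, use.names = FALSE))
  if (anyDuplicated(all_paths))
    stop("manifest paths must be distinct")
  structure(m, class = "study_manifest")
}
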