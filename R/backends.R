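#' @useDynLib magtrack, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- scaffold handling -----------------------------------------------------

# normalize scaffolds to a named DNAStringSet and validate invariants
.as_scaffolds <- function(scaffolds) {
  if (is.character(scaffolds))
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (!methods::is(scaffolds, "DNAStringSet"))
    stop("scaffolds must be a named character vector or DNAStringSet")
  if (length(scaffolds) == 0L) stop("no scaffolds produced")
  ids <- names(scaffolds)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every scaffold needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate scaffold ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(scaffolds) < 1L))
    stop("scaffolds must have length >= 1")
  scaffolds
}

#' Read scaffolds from a FASTA file
#' @param path FASTA path.
#' @return a named `DNAStringSet`.
#' @export
read_scaffolds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  .as_scaffolds(x)
}

#' Write scaffolds to a FASTA file
#' @param scaffolds named character vector or `DNAStringSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_scaffolds <- function(scaffolds, path) {
  Biostrings::writeXStringSet(.as_scaffolds(scaffolds), path)
  invisible(path)
}

# ---- assembler adapters ----------------------------------------------------

#' Assembler adapters
#'
#' The pipeline treats assembly as a pluggable backend behind a single
#' [assemble()] call. Three adapters are provided:
#'
#' * `assembler_fixture(scaffolds)` — returns the supplied scaffolds
#'   unchanged; the test fixture and the entry point for users who assembled
#'   elsewhere.
#' * `assembler_coverage(genomes, min_overlap)` — simulation-only idealised
#'   assembler: uses the simulator's per-read provenance (genome of origin
#'   and position) to emit exactly the maximal genome intervals covered by
#'   the input reads. Its output quality is limited only by read coverage,
#'   which is the property the depth-downsampling experiments probe.
#' * `assembler_external(command)` — shells out to a metagenome assembler
#'   (e.g. metaSPAdes). `command` is a function `(fastq_path, out_dir)` that
#'   must return the path of the scaffold FASTA it produced.
#'
#' @param scaffolds scaffolds for the fixture adapter.
#' @param genomes named character vector of source genome sequences
#'   (as produced by [generate_synthetic_cohort()]).
#' @param min_overlap intervals closer than this many bp are merged into one
#'   scaffold (default 1: touching/overlapping intervals only).
#' @param command external assembler launcher, see above.
#' @return an assembler adapter for [assemble()].
#' @name assemblers
NULL

#' @rdname assemblers
#' @export
assembler_fixture <- function(scaffolds) {
  scaffolds <- .as_scaffolds(scaffolds)
  structure(list(scaffolds = scaffolds),
            class = c("assembler_fixture", "assembler"))
}

#' @rdname assemblers
#' @export
assembler_coverage <- function(genomes, min_overlap = 1L) {
  stopifnot(is.character(genomes), !is.null(names(genomes)))
  structure(list(genomes = genomes, min_overlap = as.integer(min_overlap)),
            class = c("assembler_coverage", "assembler"))
}

#' @rdname assemblers
#' @export
assembler_external <- function(command) {
  stopifnot(is.function(command))
  structure(list(command = command),
            class = c("assembler_external", "assembler"))
}

#' Assemble reads into scaffolds
#'
#' Dispatches to the adapter's assembly strategy (see [assemblers]).
#'
#' @param reads a [read_set]; must be non-empty.
#' @param assembler an assembler adapter.
#' @return a named `DNAStringSet` of scaffolds.
#' @export
assemble <- function(reads, assembler) {
  stopifnot(inherits(reads, "read_set"), inherits(assembler, "assembler"))
  if (depth(reads) == 0L) stop("cannot assemble an empty read set")
  UseMethod("assemble", assembler)
}

#' @export
assemble.assembler_fixture <- function(reads, assembler) assembler$scaffolds

#' @export
assemble.assembler_coverage <- function(reads, assembler) {
  meta <- reads$meta
  if (is.null(meta) || is.null(meta$genome) || is.null(meta$pos))
    stop("coverage assembler needs simulated reads with provenance metadata")
  rl <- nchar(reads$sequence)
  out <- character(0)
  for (g in names(assembler$genomes)) {
    sel <- which(meta$genome == g)
    if (!length(sel)) next
    start <- meta$pos[sel]
    end <- start + rl[sel] - 1L
    o <- order(start)
    start <- start[o]; end <- end[o]
    # merge intervals within min_overlap into maximal covered stretches
    merged_s <- start[1L]; merged_e <- end[1L]
    ivs <- list()
    for (i in seq_along(start)[-1L]) {
      if (start[i] <= merged_e + assembler$min_overlap) {
        merged_e <- max(merged_e, end[i])
      } else {
        ivs[[length(ivs) + 1L]] <- c(merged_s, merged_e)
        merged_s <- start[i]; merged_e <- end[i]
      }
    }
    ivs[[length(ivs) + 1L]] <- c(merged_s, merged_e)
    seqs <- vapply(ivs, function(iv)
      substr(assembler$genomes[[g]], iv[1L], iv[2L]), character(1))
    names(seqs) <- sprintf("%s_s%d", g, seq_along(seqs))
    out <- c(out, seqs)
  }
  .as_scaffolds(out)
}

#' @export
assemble.assembler_external <- function(reads, assembler) {
  dir <- tempfile("assembly_")
  dir.create(dir)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(reads, fq)
  fa <- tryCatch(assembler$command(fq, dir), error = function(e)
    stop("external assembler failed: ", conditionMessage(e), call. = FALSE))
  if (!is.character(fa) || !file.exists(fa))
    stop("external assembler produced no scaffold FASTA")
  read_scaffolds(fa)
}

# ---- alignment backends ----------------------------------------------------

#' Alignment backends
#'
#' * `backend_naive()` — the built-in ungapped aligner (compiled): scans both
#'   strands of every scaffold for the best read placement by Hamming
#'   distance, using pigeonhole k-mer seeding so that every placement at or
#'   above the identity threshold is found. Needs no external binaries and is
#'   fully deterministic.
#' * `backend_external(align_cmd)` — adapter for an external short-read
#'   aligner producing SAM. `align_cmd` is a function
#'   `(reference_fasta, fastq, sam_out)` invoking the tool; the SAM is read
#'   back via its NM tag (edit distance). [backend_minimap2()] is a
#'   ready-made preset.
#'
#' @param align_cmd function launching the external aligner, see above.
#' @return a backend object accepted by [build_index()].
#' @name backends
NULL

#' @rdname backends
#' @export
backend_naive <- function() {
  structure(list(), class = c("backend_naive", "mag_backend"))
}

#' @rdname backends
#' @export
backend_external <- function(align_cmd) {
  stopifnot(is.function(align_cmd))
  structure(list(align_cmd = align_cmd),
            class = c("backend_external", "mag_backend"))
}

#' @rdname backends
#' @export
backend_minimap2 <- function() {
  backend_external(function(ref, fastq, sam_out) {
    status <- system2("minimap2",
                      c("-ax", "sr", "--secondary=no", "-N", "0",
                        shQuote(ref), shQuote(fastq)),
                      stdout = sam_out, stderr = FALSE)
    if (status != 0L) stop("minimap2 exited with status ", status)
  })
}

.as_backend <- function(backend) {
  if (inherits(backend, "mag_backend")) return(backend)
  if (is.character(backend) && length(backend) == 1L) {
    return(switch(backend,
                  naive = backend_naive(),
                  minimap2 = backend_minimap2(),
                  stop("unknown backend '", backend, "'")))
  }
  stop("backend must be a backend object or one of 'naive', 'minimap2'")
}

#' Build a source reference database from scaffolds
#'
#' Wraps the scaffolds of one source sample (donor or patient) together with
#' the alignment backend that will serve queries against them. For the
#' external backend the scaffold FASTA is materialised on disk once, so
#' repeated [align()] calls reuse it.
#'
#' @param scaffolds named character vector or `DNAStringSet` of assembled
#'   scaffolds; ids must be unique.
#' @param source_label `"donor"` or `"patient"`.
#' @param backend a backend object (see [backends]) or `"naive"`/`"minimap2"`.
#' @return an object of class `mag_db`.
#' @export
build_index <- function(scaffolds, source_label = c("donor", "patient"),
                        backend = backend_naive()) {
  source_label <- match.arg(source_label)
  scaffolds <- .as_scaffolds(scaffolds)
  backend <- .as_backend(backend)
  index <- NULL
  if (inherits(backend, "backend_external")) {
    fa <- tempfile(paste0(source_label, "_db_"), fileext = ".fasta")
    write_scaffolds(scaffolds, fa)
    index <- list(fasta = fa)
  }
  structure(list(source_label = source_label, scaffolds = scaffolds,
                 backend = backend, index = index),
            class = "mag_db")
}

#' @export
print.mag_db <- function(x, ...) {
  cat(sprintf("<mag_db> %s: %d scaffolds, %d bp total (%s backend)\n",
              x$source_label, length(x$scaffolds),
              sum(Biostrings::width(x$scaffolds)),
              class(x$backend)[1L]))
  invisible(x)
}

# per-read mismatch budget implied by an identity threshold
.mm_budget <- function(read_len, min_identity) {
  as.integer(floor((1 - min_identity) * read_len + 1e-9))
}

.new_alignment_table <- function(db_label, read_id, aligned, identity,
                                 scaffold_id) {
  structure(list(database_label = db_label, read_id = read_id,
                 aligned = aligned, identity = identity,
                 scaffold_id = scaffold_id,
                 total_reads_queried = length(read_id)),
            class = "alignment_table")
}

#' @export
print.alignment_table <- function(x, ...) {
  cat(sprintf("<alignment_table> vs %s db: %d/%d reads aligned\n",
              x$database_label, sum(x$aligned), x$total_reads_queried))
  invisible(x)
}

#' Align a read set against a source database
#'
#' Every queried read appears exactly once in the result. A read is aligned
#' iff its best hit reaches `min_identity`, with identity defined as
#' `(read length - edit distance) / read length`; sub-threshold reads are
#' recorded as unaligned. Only the single best hit per read is retained
#' (ties broken by database scaffold order, then forward strand, then
#' leftmost position).
#'
#' @param reads a [read_set].
#' @param db a `mag_db` from [build_index()].
#' @param min_identity identity threshold in (0, 1]; default 1.0 (exact).
#' @return an `alignment_table`.
#' @export
align <- function(reads, db, min_identity = 1.0) {
  stopifnot(inherits(reads, "read_set"), inherits(db, "mag_db"))
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  if (inherits(db$backend, "backend_naive")) {
    align_naive(reads, db, min_identity)
  } else {
    .align_external(reads, db, min_identity)
  }
}

#' Built-in ungapped best-hit alignment
#'
#' The naive backend's implementation, callable directly: exhaustive over all
#' placements within the mismatch budget on both strands of every scaffold
#' (see [backends]). Reads consisting only of `N` are reported unaligned.
#'
#' @inheritParams align
#' @return an `alignment_table`.
#' @export
align_naive <- function(reads, db, min_identity = 1.0) {
  n <- depth(reads)
  scafs <- as.character(db$scaffolds)
  ids <- names(db$scaffolds)
  if (n == 0L)
    return(.new_alignment_table(db$source_label, character(0), logical(0),
                                numeric(0), character(0)))
  rl <- nchar(reads$sequence)
  budget <- .mm_budget(rl, min_identity)
  # pigeonhole seed length: any placement with <= budget mismatches keeps one
  # of floor(L/k) disjoint k-mers exact when k <= floor(L/(budget+1))
  k <- min(31L, floor(min(rl / (budget + 1))))
  k <- max(1L, as.integer(k))
  res <- .seeded_align(reads$sequence, unname(scafs), budget, k)
  aligned <- !is.na(res$mismatches)
  identity <- ifelse(aligned, (rl - res$mismatches) / rl, NA_real_)
  scaffold_id <- ifelse(aligned, ids[res$scaffold], NA_character_)
  .new_alignment_table(db$source_label, reads$read_id, aligned, identity,
                       scaffold_id)
}

# external backend: FASTQ + FASTA -> tool -> SAM -> BAM -> best hits
.align_external <- function(reads, db, min_identity) {
  n <- depth(reads)
  if (n == 0L)
    return(.new_alignment_table(db$source_label, character(0), logical(0),
                                numeric(0), character(0)))
  fq <- tempfile("query_", fileext = ".fastq")
  sam <- tempfile("aln_", fileext = ".sam")
  on.exit(unlink(c(fq, sam, paste0(sam, ".bam"), paste0(sam, ".bam.bai"))))
  write_fastq(reads, fq)
  db$backend$align_cmd(db$index$fasta, fq, sam)
  if (!file.exists(sam)) stop("external aligner produced no SAM output")
  bam <- Rsamtools::asBam(sam, destination = paste0(sam, ".bam"),
                          indexDestination = FALSE, overwrite = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  rl <- stats::setNames(nchar(reads$sequence), reads$read_id)
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(b$qname))
  nm[is.na(nm)] <- 0L
  # whole-read identity: clipped bases count toward the edit distance
  clipped <- vapply(b$cigar, .cigar_clipped, integer(1), USE.NAMES = FALSE)
  edit <- nm + clipped
  idn <- (rl[b$qname] - edit) / rl[b$qname]
  # best hit per read
  o <- order(b$qname, -idn)
  first <- !duplicated(b$qname[o])
  qn <- b$qname[o][first]
  best_id <- idn[o][first]
  best_scaf <- as.character(b$rname)[o][first]
  m <- match(reads$read_id, qn)
  hit <- unname(!is.na(m) & best_id[pmax(m, 1L)] >= min_identity)
  hit[is.na(hit)] <- FALSE
  identity <- unname(ifelse(hit, best_id[m], NA_real_))
  scaffold_id <- unname(ifelse(hit, best_scaf[m], NA_character_))
  .new_alignment_table(db$source_label, reads$read_id, hit, identity,
                       scaffold_id)
}

.cigar_clipped <- function(cig) {
  if (is.na(cig)) return(0L)
  ops <- regmatches(cig, gregexpr("\\d+[SH]", cig))[[1L]]
  if (!length(ops)) return(0L)
  sum(as.integer(sub("[SH]$", "", ops)))
}
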