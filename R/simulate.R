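#' Build a simulated fosmid clone
#'
#' The circular clone molecule is the rotated vector followed by a random
#' insert, so the insert starts immediately after the MCS in circular
#' order, as in a real ligation into the MCS.
#'
#' @param vector a rotated [VectorReference-class] (e.g. [standInVector()]).
#' @param insertLength insert length in bp (fosmids carry roughly 30-40 kb).
#' @param seed RNG seed; the insert is i.i.d.-uniform A/C/G/T and
#'   deterministic per `(vector, insertLength, seed)`.
#' @param cloneId identifier.
#' @return a [SimulatedFosmid-class].
#' @export
makeFosmid <- function(vector, insertLength, seed = 1L, cloneId = "clone") {
  stopifnot(is(vector, "VectorReference"), insertLength > 0)
  if (!isRotated(vector)) stop("vector must be rotated; see rotateVector()")
  ins <- with_seed(seed, randomDna(insertLength))
  new("SimulatedFosmid", cloneId = cloneId, vector = vector,
      insert = DNAString(ins),
      circle = DNAString(paste0(as.character(vectorSequence(vector)), ins)))
}

# extract a (possibly wrapping) walk of the circle; 0-based start
.circle_walk <- function(circle, start, len) {
  C <- nchar(circle)
  reps <- ceiling((start + len) / C)
  big <- paste(rep(circle, reps), collapse = "")
  substr(big, start + 1L, start + len)
}

# per-base substitution/insertion/deletion errors (vectorised)
.apply_errors <- function(s, sub, ins, del) {
  if (sub == 0 && ins == 0 && del == 0) return(s)
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(b)
  if (del > 0) { b <- b[stats::runif(n) >= del]; n <- length(b) }
  if (n == 0L) return("")
  if (sub > 0) {
    sm <- stats::runif(n) < sub
    if (any(sm)) {
      idx <- match(b[sm], .BASES)
      b[sm] <- .BASES[((idx - 1L + sample(1:3, sum(sm), replace = TRUE)) %% 4L) + 1L]
    }
  }
  if (ins > 0) {
    ins_after <- stats::runif(n) < ins
    ni <- sum(ins_after)
    if (ni > 0L) {
      shift <- cumsum(ins_after)
      pos_orig <- seq_len(n) + c(0L, shift[-n])
      pos_ins <- which(ins_after) + shift[ins_after]
      out <- character(n + ni)
      out[pos_orig] <- b
      out[pos_ins] <- sample(.BASES, ni, replace = TRUE)
      b <- out
    }
  }
  paste(b, collapse = "")
}

# complete vector copies inside the unrolled walk [s, s+len) on a circle of
# circumference C whose vector occupies [tC, tC + vlen)
.count_vector_copies <- function(s, len, C, vlen) {
  t0 <- ceiling(s / C)
  cnt <- 0L
  t <- t0
  while (t * C + vlen <= s + len) { cnt <- cnt + 1L; t <- t + 1L }
  cnt
}

#' One rolling-circle read from a circular template
#'
#' Walks the circle from `start` for `length` bases (concatemers arise
#' naturally when the length exceeds the circumference), orients the walk
#' by `strand`, then applies per-base errors. Exposed primarily so the
#' read model is testable in isolation.
#'
#' @param circle circular template (character or DNAString), linearised at
#'   position 0.
#' @param start 0-based start position on the circle.
#' @param strand `"+"` or `"-"` (minus reads are the reverse complement of
#'   the walked template).
#' @param length read length in bases (template bases walked).
#' @param substitutionRate,insertionRate,deletionRate per-base error
#'   probabilities (applied after template extraction, drawing from the
#'   current RNG stream).
#' @return list with `sequence` and `truth`, a one-row data.frame
#'   (`start`, `end`, `strand`; `end` may exceed the circumference to
#'   denote wrapping).
#' @export
rcaReadFromCircle <- function(circle, start, strand, length,
                              substitutionRate = 0, insertionRate = 0,
                              deletionRate = 0) {
  cs <- .as_seq_char(circle)
  tmpl <- .circle_walk(cs, start, length)
  read <- if (strand == "-") .revcomp(tmpl) else tmpl
  read <- .apply_errors(read, substitutionRate, insertionRate, deletionRate)
  list(sequence = read,
       truth = data.frame(start = start, end = start + length,
                          strand = strand, stringsAsFactors = FALSE))
}

#' Simulate phi29 RCA reads from a fosmid
#'
#' Each read starts at a uniform position and strand on the circle with a
#' log-normal length (median `readLengthMedian`); the template is walked
#' circularly so reads longer than one circumference become concatemers.
#' With probability `chimeraRate` the read carries one template switch at a
#' uniform point: the walk restarts at a new uniform position, inverting
#' the strand for the configured fraction of events (the read-level
#' signature of phi29 hyper-branched products). Errors are applied per
#' base after template extraction. Truth records the error-free template
#' walk of every read.
#'
#' @param fosmid a [SimulatedFosmid-class].
#' @param config a [SimulationConfig-class].
#' @return a list:
#'   `reads` - named DNAStringSet (qualities constant, in
#'   `mcols()$quality`);
#'   `truth` - data.frame of template segments (`read_id`, `segment`,
#'   `start`, `end`, `strand`, `chimeric_junction_after`), ordered 5'
#'   to 3' along each read, intervals wrapping the circle when needed;
#'   `summary` - per-read data.frame (`read_id`, `length`,
#'   `n_segments`, `n_vector_copies`).
#' @export
simulateRcaReads <- function(fosmid, config = simulationConfig()) {
  stopifnot(is(fosmid, "SimulatedFosmid"), validObject(config))
  circle <- as.character(fosmidCircle(fosmid))
  C <- nchar(circle)
  vlen <- length(vectorSequence(fosmidVector(fosmid)))
  n <- config@nReads
  with_seed(config@seed, {
    seqs <- character(n)
    truth_rows <- base::vector("list", n)
    n_segments <- integer(n)
    n_copies <- integer(n)
    ids <- sprintf("%s_read_%05d", fosmid@cloneId, seq_len(n))
    for (i in seq_len(n)) {
      L <- max(200L, round(stats::rlnorm(1, meanlog = log(config@readLengthMedian),
                                         sdlog = config@readLengthSdLog)))
      st1 <- sample.int(C, 1L) - 1L
      sd1 <- sample(c("+", "-"), 1L)
      chim <- stats::runif(1) < config@chimeraRate
      if (!chim) {
        segs <- data.frame(start = st1, end = st1 + L, strand = sd1,
                           chimeric_junction_after = FALSE,
                           stringsAsFactors = FALSE)
      } else {
        l1 <- sample.int(L - 1L, 1L)
        st2 <- sample.int(C, 1L) - 1L
        inverted <- stats::runif(1) < config@invertedChimeraFraction
        sd2 <- if (inverted) setdiff(c("+", "-"), sd1) else sd1
        segs <- data.frame(start = c(st1, st2),
                           end = c(st1 + l1, st2 + (L - l1)),
                           strand = c(sd1, sd2),
                           chimeric_junction_after = c(TRUE, FALSE),
                           stringsAsFactors = FALSE)
      }
      pieces <- vapply(seq_len(nrow(segs)), function(j) {
        tmpl <- .circle_walk(circle, segs$start[j], segs$end[j] - segs$start[j])
        if (segs$strand[j] == "-") .revcomp(tmpl) else tmpl
      }, character(1))
      read <- .apply_errors(paste(pieces, collapse = ""),
                            config@substitutionRate, config@insertionRate,
                            config@deletionRate)
      seqs[i] <- read
      segs$read_id <- ids[i]
      segs$segment <- seq_len(nrow(segs)) - 1L
      truth_rows[[i]] <- segs
      n_segments[i] <- nrow(segs)
      n_copies[i] <- sum(vapply(seq_len(nrow(segs)), function(j)
        .count_vector_copies(segs$start[j], segs$end[j] - segs$start[j],
                             C, vlen), integer(1)))
    }
    reads <- DNAStringSet(seqs)
    names(reads) <- ids
    qc <- rawToChar(as.raw(33L + config@baseQuality))
    mcols(reads) <- S4Vectors::DataFrame(
      quality = vapply(nchar(seqs), function(w) strrep(qc, w), character(1)))
    truth <- do.call(rbind, truth_rows)
    truth <- truth[, c("read_id", "segment", "start", "end", "strand",
                       "chimeric_junction_after")]
    list(reads = reads, truth = truth,
         summary = data.frame(read_id = ids, length = nchar(seqs),
                              n_segments = n_segments,
                              n_vector_copies = n_copies,
                              stringsAsFactors = FALSE))
  })
}

#' Compare a finished insert with the simulation truth
#'
#' BLASTN-style evaluation of a finished insert against the true insert:
#' aligned-length-weighted percent identity, percent of the truth covered
#' by accepted alignments, and the signed length difference.
#'
#' @param insert an [InsertAssembly-class] or a plain sequence.
#' @param fosmid the [SimulatedFosmid-class] that generated the reads (or a
#'   plain truth sequence).
#' @return list with `identity`, `coverage_of_truth` (percent), and
#'   `length_delta` (bases, finished minus truth); all zero (with a
#'   `status` echo) when no insert was assembled.
#' @export
evaluateAgainstTruth <- function(insert, fosmid) {
  status <- if (is(insert, "InsertAssembly")) insert@status else "ok"
  seq <- if (is(insert, "InsertAssembly")) as.character(insert@insertSequence)
         else .as_seq_char(insert)
  truth <- if (is(fosmid, "SimulatedFosmid")) as.character(fosmidInsert(fosmid))
           else .as_seq_char(fosmid)
  if (!status %in% c("ok", "vector_free_contig") || !nzchar(seq))
    return(list(identity = 0, coverage_of_truth = 0, length_delta = 0,
                status = status))
  m <- findLocalMatches(seq, truth, minMatchLen = 100L, minIdentity = 70)
  if (nrow(m) == 0L)
    return(list(identity = 0, coverage_of_truth = 0,
                length_delta = nchar(seq) - nchar(truth), status = status))
  ident <- 100 * sum(m$matches) / sum(m$aln_len)
  covered <- 100 * .interval_union_len(m$rstart, m$rend) / nchar(truth)
  list(identity = ident, coverage_of_truth = covered,
       length_delta = nchar(seq) - nchar(truth), status = status)
}
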