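#' Merge nearby vector-match intervals on a read
#'
#' Nanopore indel noise fragments a single vector pass into several local
#' matches; intervals separated by at most `maxGap` bases are merged before
#' trimming so each vector pass is removed as one block.
#'
#' @param intervals a two-column matrix or data.frame of 0-based half-open
#'   `start`, `end` intervals (any order).
#' @param maxGap merge intervals separated by at most this many bases.
#' @return a data.frame of disjoint `start`, `end` intervals, ascending.
#' @examples
#' mergeVectorIntervals(cbind(c(100, 520), c(500, 900)), maxGap = 50)
#' @export
mergeVectorIntervals <- function(intervals, maxGap = 50L) {
  iv <- as.data.frame(intervals)
  if (nrow(iv) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  names(iv)[1:2] <- c("start", "end")
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  starts <- as.integer(iv$start); ends <- as.integer(iv$end)
  os <- starts[1L]; oe <- ends[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] - oe <= maxGap) oe <- max(oe, ends[i])
    else { out_s <- c(out_s, os); out_e <- c(out_e, oe)
           os <- starts[i]; oe <- ends[i] }
  }
  data.frame(start = c(out_s, os), end = c(out_e, oe))
}

#' Trim vector intervals out of a read
#'
#' The aligned (vector) regions are removed and the non-matching flanking
#' regions are retained as separate fragments, in left-to-right order. A
#' read with no vector intervals yields a single fragment spanning the
#' whole read. Any fragment shorter than `minFragmentLen` is discarded
#' (applied to whole untrimmed reads too).
#'
#' @param read a DNAString or character scalar.
#' @param vectorIntervals disjoint 0-based half-open intervals (data.frame
#'   with `start`, `end`), e.g. from [mergeVectorIntervals()].
#' @param minFragmentLen fragments shorter than this are discarded (nt).
#' @param readId parent read identifier used for fragment naming
#'   (`<parent>/<index>`, index from 0 left-to-right over kept fragments).
#' @return a [Biostrings::DNAStringSet] of fragments with metadata columns
#'   `parent_id`, `fragment_index`, `src_start`, `src_end` (0-based
#'   half-open on the parent read) and `strand` (`*` = orientation unknown
#'   here; strand normalisation happens in [processReadSet()]).
#' @export
trimRead <- function(read, vectorIntervals, minFragmentLen = 150L,
                     readId = "read") {
  s <- .as_seq_char(read)
  L <- nchar(s)
  iv <- as.data.frame(vectorIntervals)
  if (nrow(iv) > 0L) {
    names(iv)[1:2] <- c("start", "end")
    iv <- iv[order(iv$start), , drop = FALSE]
    if (any(iv$start < 0L) || any(iv$end > L) || any(iv$end <= iv$start))
      stop("vector intervals out of read bounds")
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop("vector intervals must be disjoint")
  }
  # complement of the vector intervals on [0, L)
  bounds <- c(0L, as.vector(rbind(iv$start, iv$end)), L)
  cs <- bounds[seq(1L, length(bounds), by = 2L)]
  ce <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- (ce - cs) >= minFragmentLen
  cs <- cs[keep]; ce <- ce[keep]
  seqs <- if (length(cs)) substring(s, cs + 1L, ce) else character(0)
  frs <- DNAStringSet(seqs)
  n <- length(frs)
  names(frs) <- if (n) paste0(readId, "/", seq_len(n) - 1L) else character(0)
  mcols(frs) <- S4Vectors::DataFrame(
    parent_id = rep(readId, n),
    fragment_index = if (n) seq_len(n) - 1L else integer(0),
    src_start = as.integer(cs), src_end = as.integer(ce),
    strand = rep("*", n))
  frs
}

#' De-concatenate a read set against the vector backbone
#'
#' The read-processing stage of the pipeline: each read is aligned to the
#' rotated vector; matching regions (merged when closer than the merge gap)
#' are trimmed out; non-matching flanks are retained as independent
#' fragments; fragments (and untrimmed reads) shorter than the fragment
#' filter are discarded. Fragments from reads whose vector matches lie on
#' the minus strand are reverse-complemented so all fragments from
#' vector-containing reads are in template orientation; `mcols()$strand`
#' records the read's orientation (`+`/`-`) or `*` when the read had no
#' vector match and its orientation is unknown.
#'
#' @param reads a named DNAStringSet (or character vector) of reads.
#' @param vector a rotated [VectorReference-class].
#' @param config a [PipelineConfig-class].
#' @return a list: `fragments` (DNAStringSet with the [trimRead()] metadata)
#'   and `report`, a data.frame with one row per read: `read_id`,
#'   `read_len`, `n_matches`, `bases_trimmed`, `n_fragments_kept`.
#' @export
processReadSet <- function(reads, vector, config = pipelineConfig()) {
  stopifnot(is(vector, "VectorReference"))
  if (!isRotated(vector))
    stop("vector must be rotated (MCS at the 3' end); see rotateVector()")
  rs <- .as_seq_char(reads)
  n <- length(rs)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_len(n))
  report <- data.frame(read_id = ids, read_len = nchar(rs),
                       n_matches = 0L, bases_trimmed = 0L,
                       n_fragments_kept = 0L, stringsAsFactors = FALSE)
  empty <- trimRead("A", data.frame(start = 0L, end = 1L),
                    minFragmentLen = 1L)[0]
  if (n == 0L) return(list(fragments = empty, report = report))

  vseq <- as.character(vectorSequence(vector))
  m <- findLocalMatches(rs, vseq, minMatchLen = config@minMatchLen,
                        minIdentity = config@minMatchIdentity,
                        k = config@anchorK, maxGap = config@maxChainGap)
  frag_list <- base::vector("list", n)  # `vector` arg shadows base::vector
  for (i in seq_len(n)) {
    mi <- m[m$query == i, , drop = FALSE]
    merged <- mergeVectorIntervals(mi[, c("qstart", "qend")],
                                   maxGap = config@mergeMaxGap)
    fr <- trimRead(rs[i], merged, minFragmentLen = config@minFragmentLen,
                   readId = ids[i])
    # orient fragments to the template strand: the strand carrying most
    # aligned vector bases defines the read's orientation
    if (nrow(mi) > 0L && length(fr) > 0L) {
      plus <- sum(mi$aln_len[mi$strand == "+"])
      minus <- sum(mi$aln_len[mi$strand == "-"])
      md <- mcols(fr)
      if (minus > plus) {
        fr <- reverseComplement(fr)
        names(fr) <- paste0(ids[i], "/", seq_along(fr) - 1L)
        md$strand <- rep("-", length(fr))
      } else {
        md$strand <- rep("+", length(fr))
      }
      mcols(fr) <- md
    }
    report$n_matches[i] <- nrow(mi)
    report$bases_trimmed[i] <- sum(merged$end - merged$start)
    report$n_fragments_kept[i] <- length(fr)
    frag_list[[i]] <- fr
  }
  frags <- if (any(lengths(frag_list) > 0)) do.call(c, frag_list) else empty
  list(fragments = frags, report = report)
}
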