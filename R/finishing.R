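#' Trim residual vector from the selected contig and orient the insert
#'
#' The selected contig is inspected for vector backbone matches. If the
#' dominant vector orientation is minus, the contig is reverse-complemented
#' first. Vector matches are merged as in de-concatenation and trimmed out;
#' the flanks are re-joined consistent with the expected 5' to 3' order at
#' the MCS: because the MCS sits at the vector's 3' end, the insert begins
#' immediately after the vector on the circle, so the flank downstream of
#' the vector comes first and the flank upstream of it is appended after.
#' When the contig spans more than one full circle the two flanks overlap;
#' the overlap is detected by alignment (>= 100 bp at >= 80% identity) and
#' merged into a consensus in which ties keep the first flank's base (with
#' two sequences this retains the first flank across the overlap). A
#' vector match at a contig end is trimmed without re-joining. With no
#' vector match the contig is returned unchanged with status
#' `vector_free_contig`. More than two disjoint vector blocks (a possible
#' double-backbone clone) triggers a warning; all blocks are trimmed and
#' the flanks concatenated in MCS-consistent order.
#'
#' @param contig a [Contig-class] (or character sequence).
#' @param vector a rotated [VectorReference-class].
#' @param config a [PipelineConfig-class].
#' @param cloneId clone identifier for the returned object.
#' @return an [InsertAssembly-class] carrying the finished sequence,
#'   `vectorFoundInContig`, and status `ok` or `vector_free_contig`
#'   (QC slots are zero; they are filled by [qcReport()] /
#'   [runClone()]).
#' @export
trimContigVector <- function(contig, vector, config = pipelineConfig(),
                             cloneId = NULL) {
  stopifnot(is(vector, "VectorReference"))
  cs <- if (is(contig, "Contig")) as.character(contig@sequence)
        else toupper(.as_seq_char(contig))
  if (is.null(cloneId))
    cloneId <- if (is(contig, "Contig")) contig@contigId else "contig"
  vseq <- as.character(vectorSequence(vector))
  align <- function(q) findLocalMatches(q, vseq,
                                        minMatchLen = config@minMatchLen,
                                        minIdentity = config@minMatchIdentity,
                                        k = config@anchorK,
                                        maxGap = config@maxChainGap)
  m <- align(cs)
  if (nrow(m) == 0L)
    return(.insert_assembly(cloneId, cs, vectorFound = FALSE,
                            status = "vector_free_contig"))
  # orient the contig so the vector reads forward
  if (sum(m$aln_len[m$strand == "-"]) > sum(m$aln_len[m$strand == "+"])) {
    cs <- .revcomp(cs)
    m <- align(cs)
  }
  merged <- mergeVectorIntervals(m[, c("qstart", "qend")],
                                 maxGap = config@mergeMaxGap)
  if (nrow(merged) > 2L)
    warning(sprintf(
      "%s: %d separated vector blocks in contig (possible double-backbone clone); trimming all",
      cloneId, nrow(merged)))
  L <- nchar(cs)
  # flanks: s0 before the first block, s1..sk after each block
  bounds <- c(0L, as.vector(rbind(merged$start, merged$end)), L)
  fs <- bounds[seq(1L, length(bounds), by = 2L)]
  fe <- bounds[seq(2L, length(bounds), by = 2L)]
  flanks <- substring(cs, fs + 1L, fe)
  flanks_after <- flanks[-1L]   # downstream of each vector block
  flank_before <- flanks[1L]    # upstream of the first block
  # MCS-consistent order: downstream flank(s) first, upstream flank last
  parts <- c(flanks_after, flank_before)
  parts <- parts[nzchar(parts)]
  if (nrow(merged) == 1L && nzchar(flanks_after[1L]) && nzchar(flank_before)) {
    a <- flanks_after[1L]; b <- flank_before
    ov <- findLocalMatches(b, a, minMatchLen = 100L, minIdentity = 80,
                           k = config@anchorK, maxGap = config@maxChainGap)
    ov <- ov[ov$strand == "+" & ov$qstart <= 30L &
             (nchar(a) - ov$rend) <= 30L, , drop = FALSE]
    if (nrow(ov) > 0L) {
      # contig spans >1 circle: keep flank-1 through the overlap, then the
      # non-overlapping remainder of flank-2
      ovb <- ov[which.max(ov$matches), , drop = FALSE]
      parts <- c(a, if (ovb$qend < nchar(b))
        substr(b, ovb$qend + 1L, nchar(b)) else character(0))
    }
  }
  out <- paste(parts, collapse = "")
  if (!nzchar(out))  # contig was pure vector: no insert remains
    return(.insert_assembly(cloneId, "", vectorFound = TRUE,
                            status = "no_assembly_failed"))
  .insert_assembly(cloneId, out, vectorFound = TRUE, status = "ok")
}

#' Host-contamination rule
#'
#' A contig is flagged as potentially arising from host genomic DNA when
#' its identity to the host genome exceeds `identityThreshold` percent over
#' more than `coverageThreshold` percent of its length (both strict).
#'
#' @param identity percent identity of the contig to the host genome.
#' @param coveredFraction percent of the contig length covered by host
#'   alignments.
#' @param identityThreshold,coverageThreshold strict lower bounds (defaults
#'   95 and 90).
#' @return `TRUE` or `FALSE`.
#' @examples
#' flagHostContamination(96, 92)  # TRUE
#' flagHostContamination(95, 92)  # FALSE (boundary is strict)
#' @export
flagHostContamination <- function(identity, coveredFraction,
                                  identityThreshold = 95,
                                  coverageThreshold = 90) {
  stopifnot(identity >= 0, identity <= 100,
            coveredFraction >= 0, coveredFraction <= 100)
  identity > identityThreshold && coveredFraction > coverageThreshold
}

#' Align a contig to a host genome and apply the contamination rule
#'
#' @param contigSeq contig sequence (character or DNAString).
#' @param hostSeq host genome sequence (character or DNAString).
#' @param config a [PipelineConfig-class] (supplies the strict thresholds).
#' @return list with `identity` (aligned-length-weighted percent),
#'   `coveredFraction` (percent of the contig covered by host matches) and
#'   `flag`.
#' @export
checkHostContamination <- function(contigSeq, hostSeq,
                                   config = pipelineConfig()) {
  cs <- .as_seq_char(contigSeq)
  m <- findLocalMatches(cs, .as_seq_char(hostSeq),
                        minMatchLen = config@minMatchLen,
                        minIdentity = 50,  # rule decides, not the aligner
                        k = config@anchorK, maxGap = config@maxChainGap)
  if (nrow(m) == 0L)
    return(list(identity = 0, coveredFraction = 0, flag = FALSE))
  ident <- sum(m$matches) / sum(m$aln_len) * 100
  covered <- 100 * .interval_union_len(m$qstart, m$qend) / nchar(cs)
  list(identity = ident, coveredFraction = covered,
       flag = flagHostContamination(ident, min(covered, 100),
                                    config@contaminationIdentity,
                                    config@contaminationCoverage))
}

#' QC metrics for a finished insert
#'
#' Mean depth of coverage and percent of sequenced reads contributing,
#' obtained by mapping the fragments back to the insert sequence.
#'
#' @param fragments DNAStringSet of fragments (with `parent_id` metadata
#'   from [processReadSet()]; plain sets fall back to one parent per
#'   fragment).
#' @param insert finished insert sequence.
#' @param nTotalReads total number of sequenced parent reads; defaults to
#'   the number of distinct parents among `fragments`.
#' @param config a [PipelineConfig-class] (mapping thresholds).
#' @return list with `meanDepth` (total aligned bases / insert length) and
#'   `percentReadsContributing`.
#' @export
qcReport <- function(fragments, insert, nTotalReads = NULL,
                     config = pipelineConfig()) {
  ins <- .as_seq_char(insert)
  if (!nzchar(ins)) stop("insert must be non-empty")
  if (length(fragments) == 0L)
    return(list(meanDepth = 0, percentReadsContributing = 0))
  parents <- if (!is.null(mcols(fragments)) &&
                 "parent_id" %in% colnames(mcols(fragments)))
    mcols(fragments)$parent_id else as.character(seq_along(fragments))
  if (is.null(nTotalReads)) nTotalReads <- length(unique(parents))
  mp <- mapFragments(fragments, ins, minMatchLen = config@minMatchLen,
                     minIdentity = config@minMatchIdentity,
                     k = config@anchorK, maxGap = config@maxChainGap)
  contributing <- length(unique(parents[mp$mapped]))
  list(meanDepth = mp$meanDepth,
       percentReadsContributing = 100 * contributing / max(1L, nTotalReads))
}
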