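#' Native local alignment of queries against a reference
#'
#' Finds local alignments with fixed-size k-mer anchors, collinear chaining,
#' per-gap dynamic programming and ungapped x-drop extension of the chain
#' ends. Both strands are searched. This replaces the role an external
#' whole-genome aligner plays for vector-match detection and QC mapping.
#'
#' Identity is defined once, everywhere: matching columns divided by all
#' alignment columns (gap columns included), times 100.
#'
#' @param query a character vector, DNAString or DNAStringSet of queries.
#' @param reference a single reference sequence (character or DNAString).
#' @param minMatchLen minimum aligned span on the query (bp).
#' @param minIdentity minimum percent identity.
#' @param k anchor k-mer size.
#' @param maxGap maximum gap between chained anchors (bp); also bounds the
#'   per-gap dynamic programming band.
#' @return a data.frame with one row per match, ascending by query then
#'   query start: `query` (index into the input), `qstart`, `qend`,
#'   `rstart`, `rend` (0-based half-open), `strand` (`+`/`-`, query
#'   orientation relative to the reference), `matches`, `aln_len`
#'   (alignment columns) and `identity` (percent). Queries shorter than the
#'   anchor size yield no rows.
#' @examples
#' ref <- paste(rep("ACGTTGCA", 100), collapse = "")
#' findLocalMatches(substr(ref, 101, 300), ref, minMatchLen = 50)
#' @export
findLocalMatches <- function(query, reference, minMatchLen = 100L,
                             minIdentity = 80, k = 15L, maxGap = 500L) {
  qs <- .as_seq_char(query)
  ref <- .as_seq_char(reference)
  if (length(ref) != 1L || !nzchar(ref)) stop("reference must be a single non-empty sequence")
  if (length(qs) == 0L || all(!nzchar(qs))) return(.empty_matches())
  cpp_local_matches_batch(toupper(qs), toupper(ref), k = as.integer(k),
                          min_len = as.integer(minMatchLen),
                          min_identity = as.numeric(minIdentity),
                          max_gap = as.integer(maxGap))
}

#' Map fragments onto a target and compute a depth profile
#'
#' A fragment is "mapped" iff it has at least one local match passing the
#' thresholds; depth counts reference bases covered by accepted matches.
#'
#' @param fragments DNAStringSet (or character vector) of fragments.
#' @param target single target sequence.
#' @inheritParams findLocalMatches
#' @return a list: `depth` (integer vector, one entry per target base),
#'   `mapped` (logical per fragment), `matches` (the match table),
#'   `meanDepth` (total aligned reference bases / target length).
#' @export
mapFragments <- function(fragments, target, minMatchLen = 100L,
                         minIdentity = 80, k = 15L, maxGap = 500L) {
  tg <- .as_seq_char(target)
  if (!nzchar(tg)) stop("target must be non-empty")
  L <- nchar(tg)
  n <- length(fragments)
  depth <- integer(L)
  if (n == 0L)
    return(list(depth = depth, mapped = logical(0),
                matches = .empty_matches(), meanDepth = 0))
  m <- findLocalMatches(fragments, tg, minMatchLen = minMatchLen,
                        minIdentity = minIdentity, k = k, maxGap = maxGap)
  if (nrow(m) > 0L) {
    # difference-array accumulation of [rstart, rend) coverage
    d <- numeric(L + 1L)
    for (i in seq_len(nrow(m))) {
      d[m$rstart[i] + 1L] <- d[m$rstart[i] + 1L] + 1
      d[m$rend[i] + 1L] <- d[m$rend[i] + 1L] - 1
    }
    depth <- as.integer(cumsum(d[seq_len(L)]))
  }
  mapped <- seq_len(n) %in% m$query
  list(depth = depth, mapped = mapped, matches = m,
       meanDepth = sum(m$rend - m$rstart) / L)
}

#' Export matches as PAF lines
#'
#' @param matches a match table from [findLocalMatches()].
#' @param queryNames,queryLengths name and length per query index.
#' @param refName,refLength reference name and length.
#' @return character vector of PAF lines (0-based half-open intervals,
#'   residue matches, block length).
#' @export
matchesToPaf <- function(matches, queryNames, queryLengths, refName, refLength) {
  if (nrow(matches) == 0L) return(character(0))
  sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
          queryNames[matches$query], as.integer(queryLengths[matches$query]),
          matches$qstart, matches$qend, matches$strand,
          refName, as.integer(refLength), matches$rstart, matches$rend,
          as.integer(matches$matches), as.integer(matches$aln_len), 255L)
}

#' Parse PAF lines into a match table
#'
#' @param lines character vector of PAF lines.
#' @param queryNames optional name-to-index mapping (character vector); when
#'   omitted, indices follow first appearance.
#' @return a match table in the [findLocalMatches()] schema plus a
#'   `query_name` column. Used by the pluggable external-aligner adapter.
#' @export
pafToMatches <- function(lines, queryNames = NULL) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- .empty_matches(); out$query_name <- character(0); return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(f, length, 0L) < 12L)
  if (length(bad)) stop("malformed PAF line ", bad[1L])
  qn <- vapply(f, `[[`, "", 1L)
  if (is.null(queryNames)) queryNames <- unique(qn)
  num <- function(i) as.numeric(vapply(f, `[[`, "", i))
  out <- data.frame(query = match(qn, queryNames),
                    qstart = as.integer(num(3L)), qend = as.integer(num(4L)),
                    rstart = as.integer(num(8L)), rend = as.integer(num(9L)),
                    strand = vapply(f, `[[`, "", 5L),
                    matches = num(10L), aln_len = num(11L),
                    stringsAsFactors = FALSE)
  out$identity <- ifelse(out$aln_len > 0, 100 * out$matches / out$aln_len, 0)
  out$query_name <- qn
  out[order(out$query, out$qstart), , drop = FALSE]
}
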