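#' Estimate input coverage of a fragment set
#'
#' Total fragment bases divided by the expected circular molecule size.
#' This is the quantity the assembly gate is applied to.
#'
#' @param fragments DNAStringSet (or character vector) of fragments.
#' @param expectedMoleculeSize expected molecule size in bp.
#' @return estimated x coverage (real-valued; 0 for an empty set).
#' @export
estimateInputCoverage <- function(fragments, expectedMoleculeSize = 40000L) {
  stopifnot(expectedMoleculeSize > 0)
  if (length(fragments) == 0L) return(0)
  w <- if (is(fragments, "XStringSet")) width(fragments) else nchar(fragments)
  sum(as.numeric(w)) / expectedMoleculeSize
}

#' Greedy overlap-layout-consensus assembly of vector-free fragments
#'
#' Assembly is gated on estimated input coverage: below `minInputCoverage`
#' no assembly is attempted (`no_assembly_low_coverage`). Otherwise a
#' greedy OLC is run: the longest unused fragment seeds a draft; fragments
#' with an overlap of at least `minOverlap` bp at `minOverlapIdentity`
#' percent identity (either strand) are laid onto it, the single best
#' draft-extending overhang is applied per round, and the final consensus
#' is a per-column majority vote over the layout (ties go to the
#' alphabetically first base). Leftover fragments seed further contigs.
#' Contigs whose mean layout depth falls below the gate are dropped after
#' assembly. The procedure is deterministic given `(fragments, seed)`; the
#' seed only breaks ties between equal-length seed candidates.
#'
#' @param fragments DNAStringSet (or named character vector) of fragments
#'   from one clone.
#' @param minInputCoverage the assembly gate (x).
#' @param expectedMoleculeSize expected molecule size for the coverage
#'   estimate (bp).
#' @param seed integer assembler seed.
#' @param minOverlap,minOverlapIdentity overlap acceptance thresholds.
#' @param k anchor k-mer size.
#' @param maxGap maximum anchor chaining gap (bp).
#' @param orientation optional per-fragment template orientation marks:
#'   `+`/`-` for fragments already normalised to template orientation (by
#'   [processReadSet()]), `*` for unknown. When present, each contig is
#'   reverse-complemented if the majority of its orientation-known
#'   fragments aligned to it on the minus strand, so contigs come out in
#'   template (MCS-downstream) orientation. Defaults to
#'   `mcols(fragments)$strand` when available.
#' @return an [AssemblyOutcome-class].
#' @export
assembleFragments <- function(fragments, minInputCoverage = 7,
                              expectedMoleculeSize = 40000L, seed = 1L,
                              minOverlap = 500L, minOverlapIdentity = 80,
                              k = 15L, maxGap = 500L, orientation = NULL) {
  cov <- estimateInputCoverage(fragments, expectedMoleculeSize)
  if (cov < minInputCoverage)
    return(new("AssemblyOutcome", status = "no_assembly_low_coverage",
               contigs = list(), estimatedInputCoverage = cov))
  if (is.null(orientation) && is(fragments, "DNAStringSet") &&
      !is.null(mcols(fragments)) && "strand" %in% colnames(mcols(fragments)))
    orientation <- mcols(fragments)$strand
  seqs <- toupper(.as_seq_char(fragments))
  n <- length(seqs)
  if (is.null(orientation)) orientation <- rep("*", n)
  # deterministic greedy order: length descending, seeded shuffle as tie-break
  shuffle <- with_seed(seed, sample.int(n))
  ord <- order(-nchar(seqs), shuffle)
  unused <- rep(TRUE, n)
  raw_contigs <- list()
  tig <- 0L
  while (any(unused)) {
    seed_i <- ord[unused[ord]][1L]
    draft <- seqs[seed_i]
    placed <- seed_i
    unused[seed_i] <- FALSE
    repeat {
      cand <- which(unused)
      if (length(cand) == 0L) break
      m <- cpp_local_matches_batch(seqs[cand], draft, k = as.integer(k),
                                   min_len = as.integer(minOverlap),
                                   min_identity = as.numeric(minOverlapIdentity),
                                   max_gap = as.integer(maxGap))
      if (nrow(m) == 0L) break
      progress <- FALSE
      best_ext <- NULL; best_gain <- 50L  # overhangs <= merge slack are containment
      contained <- integer(0)
      for (qi in unique(m$query)) {
        mi <- m[m$query == qi, , drop = FALSE]
        mi <- mi[which.max(mi$matches), , drop = FALSE]
        fi <- cand[qi]
        ql <- nchar(seqs[fi])
        # coordinates on the draft-oriented fragment
        if (mi$strand == "+") { oqs <- mi$qstart; oqe <- mi$qend }
        else { oqs <- ql - mi$qend; oqe <- ql - mi$qstart }
        left_ext <- if (mi$rstart <= 5L) oqs - mi$rstart else 0L
        right_ext <- if (nchar(draft) - mi$rend <= 5L)
          (ql - oqe) - (nchar(draft) - mi$rend) else 0L
        gain <- max(0L, left_ext) + max(0L, right_ext)
        if (gain > best_gain) {
          best_gain <- gain
          best_ext <- list(fi = fi, strand = mi$strand, oqs = oqs, oqe = oqe,
                           rstart = mi$rstart, rend = mi$rend,
                           left = max(0L, left_ext), right = max(0L, right_ext))
        } else if (gain <= 50L) {
          contained <- c(contained, fi)
        }
      }
      if (!is.null(best_ext)) {
        b <- best_ext
        of <- if (b$strand == "+") seqs[b$fi] else .revcomp(seqs[b$fi])
        if (b$left > 0L)
          draft <- paste0(substr(of, 1L, b$oqs - b$rstart), draft)
        if (b$right > 0L)
          draft <- paste0(draft,
                          substr(of, nchar(of) - b$right + 1L, nchar(of)))
        placed <- c(placed, b$fi)
        unused[b$fi] <- FALSE
        progress <- TRUE
      }
      if (length(contained)) {
        placed <- c(placed, contained)
        unused[contained] <- FALSE
        progress <- TRUE
      }
      if (!progress) break
    }
    tig <- tig + 1L
    id <- sprintf("tig%05d", tig)
    if (length(placed) == 1L) {
      raw_contigs[[id]] <- contig(id, draft, meanDepth = 1,
                                  nSupportingFragments = 1L)
    } else {
      cons <- cpp_consensus(draft, seqs[placed], k = as.integer(k),
                            min_len = as.integer(min(minOverlap, nchar(draft))),
                            min_identity = as.numeric(minOverlapIdentity),
                            max_gap = as.integer(maxGap))
      cseq <- cons$consensus
      # orient the contig to the template using vector-anchored fragments
      known <- orientation[placed] %in% c("+", "-") & cons$mapped
      if (any(known)) {
        minus <- sum(cons$strand[known] == "-", na.rm = TRUE)
        if (minus * 2L > sum(known)) cseq <- .revcomp(cseq)
      }
      cl <- nchar(cseq)
      raw_contigs[[id]] <- contig(
        id, cseq,
        meanDepth = sum(cons$aligned_bases) / max(1L, cl),
        nSupportingFragments = sum(cons$mapped))
    }
  }
  keep <- vapply(raw_contigs, function(ct) ct@meanDepth >= minInputCoverage,
                 logical(1))
  kept <- raw_contigs[keep]
  status <- if (length(kept) > 0L) "assembled"
            else if (length(raw_contigs) > 0L) "no_assembly_low_coverage"
            else "no_assembly_failed"
  new("AssemblyOutcome", status = status, contigs = unname(kept),
      estimatedInputCoverage = cov)
}

#' Select the primary contig
#'
#' Operationalises "highest length and coverage" as the contig maximising
#' `length x mean depth`; ties broken by greater length, then by
#' lexicographically smaller contig id.
#'
#' @param x an [AssemblyOutcome-class] or a list of [Contig-class] objects.
#' @return the selected [Contig-class].
#' @export
selectPrimaryContig <- function(x) {
  cts <- if (is(x, "AssemblyOutcome")) contigs(x) else x
  if (length(cts) == 0L)
    stop("no contigs to select from (no assembly)")
  len <- vapply(cts, function(ct) length(ct@sequence), numeric(1))
  dep <- vapply(cts, function(ct) ct@meanDepth, numeric(1))
  ids <- vapply(cts, function(ct) ct@contigId, character(1))
  score <- len * dep
  o <- order(-score, -len, ids)
  cts[[o[1L]]]
}
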