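#' Rotate a circular vector so the MCS sits at the 3' end
#'
#' The vector backbone is circular; all trimming arithmetic in this package
#' assumes a linearisation in which the multiple-cloning site occupies the
#' final bases, so that in circular order the cloned insert begins
#' immediately after the stored sequence. This function performs that
#' circular permutation: `rotated = S[mcsEnd:] + S[:mcsEnd]` (0-based,
#' half-open).
#'
#' @param rawSequence vector backbone as character or DNAString
#'   (A/C/G/T/N only).
#' @param mcsInterval 0-based half-open MCS interval `c(start, end)` on the
#'   raw sequence.
#' @param name identifier for the returned reference.
#' @return a rotated [VectorReference-class]; its MCS interval ends at the
#'   final base.
#' @examples
#' rv <- rotateVector("AAACCCGGGTTT", c(3, 6))
#' as.character(vectorSequence(rv))  # "GGGTTTAAACCC"
#' mcsInterval(rv)                   # 9 12
#' @export
rotateVector <- function(rawSequence, mcsInterval, name = "vector") {
  s <- toupper(.as_seq_char(rawSequence))
  if (length(s) != 1L || !.check_dna(s))
    stop("vector sequence must be a single non-empty string over {A,C,G,T,N}")
  L <- nchar(s)
  ms <- as.integer(mcsInterval[1L]); me <- as.integer(mcsInterval[2L])
  if (is.na(ms) || is.na(me) || ms < 0L || me > L || ms >= me)
    stop(sprintf("MCS interval [%s,%s) out of bounds for a %d bp sequence",
                 mcsInterval[1L], mcsInterval[2L], L))
  rotated <- if (me == L) s else
    paste0(substr(s, me + 1L, L), substr(s, 1L, me))
  vectorReference(name, rotated, L - (me - ms), L, isRotated = TRUE)
}

#' Read a vector backbone from FASTA and rotate it
#'
#' @param path single-record FASTA file.
#' @param mcsInterval 0-based half-open MCS interval on the stored record.
#' @param name optional name (defaults to the FASTA record id).
#' @return a rotated [VectorReference-class].
#' @export
readVectorFasta <- function(path, mcsInterval, name = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("vector FASTA must contain exactly one record, found ", length(seqs))
  if (is.null(name)) name <- sub("\\s.*$", "", names(seqs)[1L])
  rotateVector(as.character(seqs[[1L]]), mcsInterval, name = name)
}

#' In-silico restriction digestion
#'
#' Scans recognition sites on the top strand only (sufficient for the
#' palindromic SacI/XhoI sites) and returns the multiset of fragment
#' lengths. For a circular molecule with k >= 1 cuts this yields k
#' fragments; for a linear molecule, k + 1. An uncut circular molecule
#' yields a single fragment of the full length.
#'
#' @param sequence DNA sequence (character, DNAString, or
#'   [VectorReference-class]).
#' @param topology `"circular"` or `"linear"`.
#' @param enzymes list of [RestrictionEnzyme-class] objects (possibly empty).
#' @return integer vector of fragment lengths, descending; lengths always
#'   sum to the molecule length.
#' @examples
#' digestSequence("GAGCTCAAAACTCGAG", "circular", commonEnzymes())  # 10 6
#' @export
digestSequence <- function(sequence, topology = c("circular", "linear"),
                           enzymes = commonEnzymes()) {
  topology <- match.arg(topology)
  if (is(sequence, "VectorReference")) sequence <- vectorSequence(sequence)
  s <- toupper(.as_seq_char(sequence))
  L <- nchar(s)
  if (L == 0L) stop("cannot digest an empty sequence")
  cuts <- integer(0)
  for (e in enzymes) {
    rec <- e@recognition
    rl <- nchar(rec)
    scan <- if (topology == "circular" && rl > 1L)
      paste0(s, substr(s, 1L, rl - 1L)) else s
    hits <- gregexpr(rec, scan, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    sites <- as.integer(hits) - 1L          # 0-based site starts
    sites <- sites[sites < L]               # drop wrap-around duplicates
    cc <- sites + e@cutOffset
    if (topology == "circular") cc <- cc %% L
    cuts <- c(cuts, cc)
  }
  cuts <- sort(unique(cuts))
  frags <- if (topology == "circular") {
    if (length(cuts) == 0L) L else diff(c(cuts, cuts[1L] + L))
  } else {
    diff(c(0L, cuts[cuts > 0L & cuts < L], L))
  }
  sort(as.integer(frags[frags > 0L]), decreasing = TRUE)
}

#' Tabulate an in-silico digest
#'
#' @inheritParams digestSequence
#' @param name molecule name for the table row.
#' @return a data.frame with columns `molecule`, `enzymes`, `n_fragments`,
#'   `fragment_lengths` (comma-separated, descending) suitable for
#'   tab-separated output.
#' @export
digestTable <- function(sequence, topology = c("circular", "linear"),
                        enzymes = commonEnzymes(), name = "molecule") {
  frags <- digestSequence(sequence, topology, enzymes)
  data.frame(molecule = name,
             enzymes = paste(vapply(enzymes, function(e) e@name, ""),
                             collapse = "+"),
             n_fragments = length(frags),
             fragment_lengths = paste(frags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Synthetic stand-in vector backbone
#'
#' The true pCC1FOS backbone sequence is not bundled; this generates a
#' deterministic synthetic stand-in of comparable size for tests and
#' simulations: a random backbone carrying the pCC1 amplification primer
#' sites, exactly one SacI and one XhoI site, and a designated MCS at the
#' 3' end (already rotated). Any real vector can be supplied instead via
#' [readVectorFasta()].
#'
#' @param length backbone length in bp (default 8000, roughly pCC1FOS).
#' @param mcsLen length of the designated MCS at the 3' end.
#' @return a rotated [VectorReference-class] named
#'   `"standin_vector_synthetic"`.
#' @export
standInVector <- function(length = 8000L, mcsLen = 60L) {
  length <- as.integer(length)
  stopifnot(length >= 1000L, mcsLen < length)
  with_seed(190524L, {
    s <- randomDna(length)
    pr <- pcc1Primers()
    # embed the backbone primer sites (forward strand + reverse primer site)
    s <- .plant(s, pr@forward, length %/% 8L)
    s <- .plant(s, .revcomp(pr@reverse), length %/% 2L)
    # exactly one SacI and one XhoI site, clear of primers and MCS
    sac_at <- length %/% 4L
    xho_at <- min(5L * length %/% 8L, length - mcsLen - 100L)
    s <- .plant(s, "GAGCTC", sac_at)
    s <- .plant(s, "CTCGAG", xho_at)
    protected <- c(seq(length %/% 8L, length.out = nchar(pr@forward)),
                   seq(length %/% 2L, length.out = nchar(pr@reverse)),
                   seq(sac_at, length.out = 6L), seq(xho_at, length.out = 6L))
    for (pass in 1:10) {  # scrubbing one site may spawn the other
      s <- .scrub_site(s, "GAGCTC", keep_at = sac_at, protected = protected)
      s <- .scrub_site(s, "CTCGAG", keep_at = xho_at, protected = protected)
      n_sac <- length(gregexpr("GAGCTC", s, fixed = TRUE)[[1L]])
      n_xho <- length(gregexpr("CTCGAG", s, fixed = TRUE)[[1L]])
      if (n_sac == 1L && n_xho == 1L) break
    }
    vectorReference("standin_vector_synthetic", s,
                    length - mcsLen, length, isRotated = TRUE)
  })
}

# overwrite s[at..] with the motif (1-based position)
.plant <- function(s, motif, at) {
  paste0(substr(s, 1L, at - 1L), motif,
         substr(s, at + nchar(motif), nchar(s)))
}

# mutate one base of every stray occurrence of a site until only the copy
# at keep_at (if any) remains, never touching protected positions
.scrub_site <- function(s, site, keep_at = NA_integer_, protected = integer(0)) {
  for (i in 1:200) {
    hits <- gregexpr(site, s, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(s)
    strays <- as.integer(hits)
    if (!is.na(keep_at)) strays <- strays[strays != keep_at]
    if (length(strays) == 0L) return(s)
    pos <- seq(strays[1L], length.out = nchar(site))
    pos <- setdiff(pos, protected)
    if (length(pos) == 0L) stop("cannot scrub site overlapping a feature")
    p <- pos[(length(pos) + 1L) %/% 2L]
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(.BASES, cur)[1L]
  }
  stop("failed to scrub restriction site ", site)
}
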