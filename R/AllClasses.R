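#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet BStringSet width reverseComplement
#' @importFrom S4Vectors mcols mcols<-
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  nzchar(x) && grepl(pat, x)
}

# ---------------------------------------------------------------------------
# VectorReference
# ---------------------------------------------------------------------------

#' Vector backbone reference
#'
#' Holds the cloning-vector backbone sequence rotated so that the
#' multiple-cloning site (MCS) occupies the final bases. All trimming and
#' insert orientation is anchored on this object. Coordinates are 0-based,
#' half-open.
#'
#' @slot name single identifier.
#' @slot sequence a [Biostrings::DNAString] over A/C/G/T/N.
#' @slot mcsStart,mcsEnd 0-based half-open MCS interval on the stored
#'   (rotated) sequence.
#' @slot isRotated `TRUE` when the MCS ends at the final base.
#' @exportClass VectorReference
setClass("VectorReference",
  representation(name = "character", sequence = "DNAString",
                 mcsStart = "integer", mcsEnd = "integer",
                 isRotated = "logical"))

setValidity("VectorReference", function(object) {
  s <- as.character(object@sequence)
  L <- nchar(s)
  if (!.check_dna(s)) return("sequence must be non-empty over {A,C,G,T,N}")
  if (object@mcsStart < 0L || object@mcsEnd > L || object@mcsStart >= object@mcsEnd)
    return("mcs interval must be non-empty and within [0, length)")
  if (isTRUE(object@isRotated) && object@mcsEnd != L)
    return("rotated vector must carry the MCS at the 3' end (mcsEnd == length)")
  TRUE
})

#' Construct a VectorReference
#'
#' @param name identifier.
#' @param sequence character or DNAString (A/C/G/T/N).
#' @param mcsStart,mcsEnd 0-based half-open MCS interval.
#' @param isRotated whether the sequence already has the MCS at its 3' end.
#' @return a [VectorReference-class] object.
#' @seealso [rotateVector()] which builds a rotated reference from an
#'   arbitrary circular permutation.
#' @export
vectorReference <- function(name, sequence, mcsStart, mcsEnd, isRotated = FALSE) {
  s <- toupper(as.character(sequence))
  if (!.check_dna(s))
    stop("vector sequence must be non-empty over {A,C,G,T,N}")
  new("VectorReference", name = as.character(name), sequence = DNAString(s),
      mcsStart = as.integer(mcsStart), mcsEnd = as.integer(mcsEnd),
      isRotated = isRotated)
}

#' @describeIn vectorReference sequence accessor (returns a DNAString).
#' @param x a `VectorReference`.
#' @export
vectorSequence <- function(x) x@sequence

#' @describeIn vectorReference MCS interval accessor; 0-based half-open
#'   `c(start, end)`.
#' @export
mcsInterval <- function(x) c(x@mcsStart, x@mcsEnd)

#' @describeIn vectorReference rotation flag accessor.
#' @export
isRotated <- function(x) x@isRotated

setMethod("show", "VectorReference", function(object) {
  cat(sprintf("VectorReference '%s': %d bp, MCS [%d,%d)%s\n",
              object@name, length(object@sequence),
              object@mcsStart, object@mcsEnd,
              if (object@isRotated) ", rotated (MCS at 3' end)" else ""))
})

# ---------------------------------------------------------------------------
# PrimerPair / RestrictionEnzyme
# ---------------------------------------------------------------------------

#' Amplification primer pair
#'
#' Backbone-specific primers used for rolling-circle amplification
#' (phosphorothioate marks stripped).
#'
#' @slot forward,reverse DNA strings.
#' @exportClass PrimerPair
setClass("PrimerPair", representation(forward = "character", reverse = "character"))

setValidity("PrimerPair", function(object) {
  if (!.check_dna(object@forward) || !.check_dna(object@reverse))
    return("primers must be non-empty DNA strings")
  TRUE
})

#' The standard pCC1 backbone amplification primers
#'
#' Returns the pCC1 forward (27 nt) and reverse (26 nt) primers used for
#' backbone-specific rolling-circle amplification of fosmid clones, with
#' phosphorothioate marks stripped.
#'
#' @return a [PrimerPair-class].
#' @export
pcc1Primers <- function() {
  new("PrimerPair",
      forward = "GGATGTGCTGCAAGGCGATTAAGTTGG",
      reverse = "CTCGTATGTTGTGTGGAATTGTGAGC")
}

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair: forward %d nt, reverse %d nt\n",
              nchar(object@forward), nchar(object@reverse)))
})

#' Restriction enzyme description
#'
#' Only palindromic recognition sites scanned on the top strand are
#' supported (sufficient for SacI and XhoI).
#'
#' @slot name identifier.
#' @slot recognition recognition site, top strand.
#' @slot cutOffset 0-based offset of the top-strand cut within the site.
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  if (!.check_dna(object@recognition, allow_n = FALSE))
    return("recognition site must be a DNA string")
  if (object@cutOffset < 0L || object@cutOffset > nchar(object@recognition))
    return("cutOffset must lie within [0, nchar(recognition)]")
  TRUE
})

#' @rdname RestrictionEnzyme-class
#' @param name,recognition,cutOffset see slots.
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = as.character(name),
      recognition = toupper(as.character(recognition)),
      cutOffset = as.integer(cutOffset))
}

#' @rdname RestrictionEnzyme-class
#' @return `commonEnzymes()`: named list with SacI (GAGCT^C) and
#'   XhoI (C^TCGAG).
#' @export
commonEnzymes <- function() {
  list(SacI = restrictionEnzyme("SacI", "GAGCTC", 5L),
       XhoI = restrictionEnzyme("XhoI", "CTCGAG", 1L))
}

setMethod("show", "RestrictionEnzyme", function(object) {
  r <- object@recognition
  cat(sprintf("RestrictionEnzyme %s: %s^%s\n", object@name,
              substr(r, 1, object@cutOffset),
              substr(r, object@cutOffset + 1, nchar(r))))
})

# ---------------------------------------------------------------------------
# Contig / AssemblyOutcome
# ---------------------------------------------------------------------------

#' Assembled contig
#'
#' @slot contigId identifier.
#' @slot sequence consensus sequence ([Biostrings::DNAString]).
#' @slot meanDepth mean fragment depth of coverage (x).
#' @slot nSupportingFragments number of fragments in the layout.
#' @exportClass Contig
setClass("Contig",
  representation(contigId = "character", sequence = "DNAString",
                 meanDepth = "numeric", nSupportingFragments = "integer"))

setValidity("Contig", function(object) {
  if (length(object@sequence) == 0L) return("contig sequence must be non-empty")
  if (object@meanDepth <= 0) return("meanDepth must be > 0")
  if (object@nSupportingFragments < 1L) return("need >= 1 supporting fragment")
  TRUE
})

#' @rdname Contig-class
#' @param contigId,sequence,meanDepth,nSupportingFragments see slots.
#' @export
contig <- function(contigId, sequence, meanDepth, nSupportingFragments) {
  new("Contig", contigId = contigId, sequence = DNAString(as.character(sequence)),
      meanDepth = as.numeric(meanDepth),
      nSupportingFragments = as.integer(nSupportingFragments))
}

#' @rdname Contig-class
#' @param x a `Contig`.
#' @export
contigId <- function(x) x@contigId

#' @rdname Contig-class
#' @export
contigSequence <- function(x) x@sequence

#' @rdname Contig-class
#' @export
meanDepth <- function(x) x@meanDepth

#' @rdname Contig-class
#' @export
supportCount <- function(x) x@nSupportingFragments

setMethod("show", "Contig", function(object) {
  cat(sprintf("Contig %s: %d bp, mean depth %.1fx, %d fragments\n",
              object@contigId, length(object@sequence), object@meanDepth,
              object@nSupportingFragments))
})

.ASSEMBLY_STATUSES <- c("assembled", "no_assembly_low_coverage", "no_assembly_failed")

#' Result of the assembly stage
#'
#' @slot status one of `assembled`, `no_assembly_low_coverage`,
#'   `no_assembly_failed`.
#' @slot contigs list of [Contig-class] objects.
#' @slot estimatedInputCoverage total fragment bases divided by the expected
#'   molecule size (x coverage).
#' @exportClass AssemblyOutcome
setClass("AssemblyOutcome",
  representation(status = "character", contigs = "list",
                 estimatedInputCoverage = "numeric"))

setValidity("AssemblyOutcome", function(object) {
  if (!object@status %in% .ASSEMBLY_STATUSES)
    return(sprintf("status must be one of %s", paste(.ASSEMBLY_STATUSES, collapse = ", ")))
  if (object@status == "assembled" && length(object@contigs) < 1L)
    return("assembled outcome must carry >= 1 contig")
  TRUE
})

#' @rdname AssemblyOutcome-class
#' @param x an `AssemblyOutcome` (or `InsertAssembly` for `assemblyStatus`).
#' @export
assemblyStatus <- function(x) x@status

#' @rdname AssemblyOutcome-class
#' @export
contigs <- function(x) x@contigs

#' @rdname AssemblyOutcome-class
#' @export
estimatedInputCoverage <- function(x) x@estimatedInputCoverage

setMethod("show", "AssemblyOutcome", function(object) {
  cat(sprintf("AssemblyOutcome: %s, %d contig(s), estimated input coverage %.2fx\n",
              object@status, length(object@contigs),
              object@estimatedInputCoverage))
})

# ---------------------------------------------------------------------------
# InsertAssembly
# ---------------------------------------------------------------------------

.INSERT_STATUSES <- c("ok", "vector_free_contig",
                      "no_assembly_low_coverage", "no_assembly_failed")

#' Finished clone insert with QC
#'
#' The finished, MCS-oriented linear insert of one clone together with its
#' quality metrics.
#'
#' @slot cloneId identifier.
#' @slot insertSequence finished linear insert (may be empty when no
#'   assembly was produced).
#' @slot vectorFoundInContig whether residual vector was detected in the
#'   selected contig.
#' @slot meanDepth mean depth of coverage from mapping fragments back.
#' @slot percentReadsContributing percent of sequenced reads with at least
#'   one fragment mapping to the insert.
#' @slot contaminationFlag `TRUE`/`FALSE` from the host-contamination rule,
#'   `NA` when no host genome was supplied.
#' @slot status `ok`, `vector_free_contig`, `no_assembly_low_coverage` or
#'   `no_assembly_failed`.
#' @exportClass InsertAssembly
setClass("InsertAssembly",
  representation(cloneId = "character", insertSequence = "DNAString",
                 vectorFoundInContig = "logical", meanDepth = "numeric",
                 percentReadsContributing = "numeric",
                 contaminationFlag = "logical", status = "character"))

setValidity("InsertAssembly", function(object) {
  if (!object@status %in% .INSERT_STATUSES)
    return(sprintf("status must be one of %s", paste(.INSERT_STATUSES, collapse = ", ")))
  if (object@status %in% c("ok", "vector_free_contig") &&
      length(object@insertSequence) == 0L)
    return("insert sequence must be non-empty when an insert was produced")
  if (!is.na(object@percentReadsContributing) &&
      (object@percentReadsContributing < 0 || object@percentReadsContributing > 100))
    return("percentReadsContributing must lie in [0, 100]")
  if (!is.na(object@meanDepth) && object@meanDepth < 0)
    return("meanDepth must be >= 0")
  TRUE
})

.insert_assembly <- function(cloneId, insertSequence = "", vectorFound = FALSE,
                             meanDepth = 0, percentReads = 0,
                             contamination = NA, status = "ok") {
  new("InsertAssembly", cloneId = cloneId,
      insertSequence = DNAString(as.character(insertSequence)),
      vectorFoundInContig = vectorFound, meanDepth = as.numeric(meanDepth),
      percentReadsContributing = as.numeric(percentReads),
      contaminationFlag = as.logical(contamination), status = status)
}

#' @rdname InsertAssembly-class
#' @param x an `InsertAssembly`.
#' @export
insertSequence <- function(x) x@insertSequence

#' @rdname InsertAssembly-class
#' @export
cloneId <- function(x) x@cloneId

#' @rdname InsertAssembly-class
#' @export
percentReadsContributing <- function(x) x@percentReadsContributing

#' @rdname InsertAssembly-class
#' @export
contaminationFlag <- function(x) x@contaminationFlag

#' @rdname InsertAssembly-class
#' @export
vectorFoundInContig <- function(x) x@vectorFoundInContig

setMethod("show", "InsertAssembly", function(object) {
  cat(sprintf("InsertAssembly %s: status %s, %d bp, depth %.1fx, %.1f%% reads%s\n",
              object@cloneId, object@status, length(object@insertSequence),
              object@meanDepth, object@percentReadsContributing,
              if (isTRUE(object@contaminationFlag)) ", HOST CONTAMINATION" else ""))
})

# ---------------------------------------------------------------------------
# SimulatedFosmid
# ---------------------------------------------------------------------------

#' Simulated circular fosmid molecule
#'
#' The circle is the rotated vector followed by the insert, so the insert
#' begins immediately after the MCS in circular order.
#'
#' @slot cloneId identifier.
#' @slot vector the [VectorReference-class] backbone.
#' @slot insert true insert sequence.
#' @slot circle full circular molecule (vector then insert), stored
#'   linearised at the vector start.
#' @exportClass SimulatedFosmid
setClass("SimulatedFosmid",
  representation(cloneId = "character", vector = "VectorReference",
                 insert = "DNAString", circle = "DNAString"))

setValidity("SimulatedFosmid", function(object) {
  if (length(object@circle) !=
      length(vectorSequence(object@vector)) + length(object@insert))
    return("circumference must equal vector length + insert length")
  vlen <- length(vectorSequence(object@vector))
  if (as.character(object@circle[seq_len(vlen)]) !=
      as.character(vectorSequence(object@vector)))
    return("circle must begin with the vector sequence")
  TRUE
})

#' @rdname SimulatedFosmid-class
#' @param x a `SimulatedFosmid`.
#' @export
fosmidInsert <- function(x) x@insert

#' @rdname SimulatedFosmid-class
#' @export
fosmidCircle <- function(x) x@circle

#' @rdname SimulatedFosmid-class
#' @export
fosmidVector <- function(x) x@vector

#' @rdname SimulatedFosmid-class
#' @export
circumference <- function(x) length(x@circle)

setMethod("show", "SimulatedFosmid", function(object) {
  cat(sprintf("SimulatedFosmid %s: %d bp vector + %d bp insert = %d bp circle\n",
              object@cloneId, length(vectorSequence(object@vector)),
              length(object@insert), length(object@circle)))
})

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Read-simulation parameters
#'
#' Defaults emulate an R10.4.1-style nanopore run of phi29
#' rolling-circle-amplified fosmids: log-normal read lengths with median
#' 11,500 bp, ~1% total error (0.5% substitutions, 0.25% insertions, 0.25%
#' deletions) and a 2% per-read chimera (template switch) rate of which half
#' are inverted junctions.
#'
#' @slot seed RNG seed (integer).
#' @slot nReads number of reads.
#' @slot readLengthMedian median read length in bases.
#' @slot readLengthSdLog log-scale standard deviation of the read-length
#'   log-normal.
#' @slot substitutionRate,insertionRate,deletionRate per-base error
#'   probabilities.
#' @slot chimeraRate per-read probability of one template switch.
#' @slot invertedChimeraFraction fraction of chimeric junctions that invert
#'   the template strand.
#' @slot baseQuality constant Phred score written to FASTQ output.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seed = "integer", nReads = "integer",
                 readLengthMedian = "numeric", readLengthSdLog = "numeric",
                 substitutionRate = "numeric", insertionRate = "numeric",
                 deletionRate = "numeric", chimeraRate = "numeric",
                 invertedChimeraFraction = "numeric", baseQuality = "integer"))

setValidity("SimulationConfig", function(object) {
  rates <- c(object@substitutionRate, object@insertionRate,
             object@deletionRate, object@chimeraRate,
             object@invertedChimeraFraction)
  if (any(rates < 0 | rates > 1)) return("all rates must lie in [0, 1]")
  if (object@nReads <= 0L) return("nReads must be > 0")
  if (object@readLengthMedian <= 0) return("readLengthMedian must be > 0")
  TRUE
})

#' @rdname SimulationConfig-class
#' @param seed,nReads,readLengthMedian,readLengthSdLog,substitutionRate,insertionRate,deletionRate,chimeraRate,invertedChimeraFraction,baseQuality
#'   see slots.
#' @export
simulationConfig <- function(seed = 1L, nReads = 100L,
                             readLengthMedian = 11500,
                             readLengthSdLog = 0.35,
                             substitutionRate = 0.005,
                             insertionRate = 0.0025,
                             deletionRate = 0.0025,
                             chimeraRate = 0.02,
                             invertedChimeraFraction = 0.5,
                             baseQuality = 20L) {
  new("SimulationConfig", seed = as.integer(seed), nReads = as.integer(nReads),
      readLengthMedian = readLengthMedian, readLengthSdLog = readLengthSdLog,
      substitutionRate = substitutionRate, insertionRate = insertionRate,
      deletionRate = deletionRate, chimeraRate = chimeraRate,
      invertedChimeraFraction = invertedChimeraFraction,
      baseQuality = as.integer(baseQuality))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d reads, median %d bp (sdlog %.2f), ",
                     "errors sub %.3g ins %.3g del %.3g, chimera %.3g ",
                     "(%.0f%% inverted), seed %d\n"),
              object@nReads, round(object@readLengthMedian),
              object@readLengthSdLog, object@substitutionRate,
              object@insertionRate, object@deletionRate, object@chimeraRate,
              100 * object@invertedChimeraFraction, object@seed))
})

# ---------------------------------------------------------------------------
# PipelineConfig
# ---------------------------------------------------------------------------

#' Pipeline thresholds
#'
#' All tunables of the per-clone pipeline. The 150 nt fragment filter, the
#' coverage-7 assembly gate and the 95%/90% host-contamination rule are the
#' published operating points; the remaining defaults are this package's
#' design choices (see the methods vignette).
#'
#' @slot minMatchLen minimum query span of an accepted vector match (bp).
#' @slot minMatchIdentity minimum percent identity of an accepted match.
#' @slot mergeMaxGap adjacent vector matches closer than this are merged (bp).
#' @slot minFragmentLen reads/fragments shorter than this are discarded (nt).
#' @slot minInputCoverage assembly proceeds only at or above this estimated
#'   input coverage; contigs below it are dropped after assembly (x).
#' @slot expectedMoleculeSize expected circular molecule size used for the
#'   coverage estimate (bp).
#' @slot minOverlap,minOverlapIdentity overlap acceptance thresholds of the
#'   greedy assembler.
#' @slot contaminationIdentity,contaminationCoverage strict lower bounds of
#'   the host-contamination rule (percent).
#' @slot anchorK k-mer anchor size of the native aligner.
#' @slot maxChainGap maximum gap between chained anchors (bp).
#' @slot seed assembler seed.
#' @slot externalAssemblerCmd optional command template for an external
#'   assembler (empty string = use the native assembler).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(minMatchLen = "integer", minMatchIdentity = "numeric",
                 mergeMaxGap = "integer", minFragmentLen = "integer",
                 minInputCoverage = "numeric", expectedMoleculeSize = "integer",
                 minOverlap = "integer", minOverlapIdentity = "numeric",
                 contaminationIdentity = "numeric",
                 contaminationCoverage = "numeric",
                 anchorK = "integer", maxChainGap = "integer",
                 seed = "integer", externalAssemblerCmd = "character"))

setValidity("PipelineConfig", function(object) {
  pos <- c(object@minMatchLen, object@mergeMaxGap + 1L, object@minFragmentLen,
           object@minInputCoverage, object@expectedMoleculeSize,
           object@minOverlap, object@anchorK, object@maxChainGap)
  if (any(pos <= 0)) return("all thresholds must be positive")
  pct <- c(object@minMatchIdentity, object@minOverlapIdentity,
           object@contaminationIdentity, object@contaminationCoverage)
  if (any(pct <= 0 | pct > 100)) return("percent thresholds must lie in (0, 100]")
  TRUE
})

#' @rdname PipelineConfig-class
#' @param minMatchLen,minMatchIdentity,mergeMaxGap,minFragmentLen,minInputCoverage,expectedMoleculeSize,minOverlap,minOverlapIdentity,contaminationIdentity,contaminationCoverage,anchorK,maxChainGap,seed,externalAssemblerCmd
#'   see slots.
#' @export
pipelineConfig <- function(minMatchLen = 100L, minMatchIdentity = 80,
                           mergeMaxGap = 50L, minFragmentLen = 150L,
                           minInputCoverage = 7, expectedMoleculeSize = 40000L,
                           minOverlap = 500L, minOverlapIdentity = 80,
                           contaminationIdentity = 95,
                           contaminationCoverage = 90,
                           anchorK = 15L, maxChainGap = 500L, seed = 1L,
                           externalAssemblerCmd = "") {
  new("PipelineConfig",
      minMatchLen = as.integer(minMatchLen),
      minMatchIdentity = as.numeric(minMatchIdentity),
      mergeMaxGap = as.integer(mergeMaxGap),
      minFragmentLen = as.integer(minFragmentLen),
      minInputCoverage = as.numeric(minInputCoverage),
      expectedMoleculeSize = as.integer(expectedMoleculeSize),
      minOverlap = as.integer(minOverlap),
      minOverlapIdentity = as.numeric(minOverlapIdentity),
      contaminationIdentity = as.numeric(contaminationIdentity),
      contaminationCoverage = as.numeric(contaminationCoverage),
      anchorK = as.integer(anchorK), maxChainGap = as.integer(maxChainGap),
      seed = as.integer(seed),
      externalAssemblerCmd = as.character(externalAssemblerCmd))
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(paste0("PipelineConfig: vector match >= %d bp @ >= %.0f%% id, ",
                     "merge gap %d, fragment filter %d nt, coverage gate %.0fx ",
                     "(expected %d bp), overlap >= %d bp @ >= %.0f%%\n"),
              object@minMatchLen, object@minMatchIdentity, object@mergeMaxGap,
              object@minFragmentLen, object@minInputCoverage,
              object@expectedMoleculeSize, object@minOverlap,
              object@minOverlapIdentity))
})
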