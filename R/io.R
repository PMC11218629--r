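#' Read sequences from FASTA or FASTQ
#'
#' Format is detected from content when `format = "auto"` (gzip
#' transparent). FASTQ qualities are kept in `mcols()$quality`.
#'
#' @param path input file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return a named DNAStringSet; FASTQ input carries a `quality` metadata
#'   column.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    first <- readLines(con, n = 1L)
    if (length(first) == 0L) stop("empty sequence file: ", path)
    format <- if (startsWith(first, ">")) "fasta"
              else if (startsWith(first, "@")) "fastq"
              else stop("cannot detect format of ", path,
                        " (expected '>' or '@' on the first line)")
  }
  if (format == "fasta") {
    out <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("FASTA parse error in ", path,
                                             ": ", conditionMessage(e)))
  } else {
    out <- tryCatch({
      x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      q <- mcols(x)$qualities
      ql <- width(q)
      bad <- which(ql != width(x))
      if (length(bad))
        stop("record ", bad[1L], " has quality length ", ql[bad[1L]],
             " != sequence length ", width(x)[bad[1L]])
      mcols(x) <- S4Vectors::DataFrame(quality = as.character(q))
      x
    }, error = function(e) stop("FASTQ parse error in ", path, ": ",
                                conditionMessage(e)))
  }
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a named DNAStringSet. For FASTQ, per-record qualities are taken
#'   from `mcols(x)$quality` when present, else a constant Phred score is
#'   used.
#' @param path output file (format defaults from the extension:
#'   `.fq`/`.fastq` write FASTQ).
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @param baseQuality constant Phred score used when no qualities are
#'   attached.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(x, path, format = c("auto", "fasta", "fastq"),
                           baseQuality = 20L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- as(x, "DNAStringSet")
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    q <- if (!is.null(mcols(x)) && "quality" %in% colnames(mcols(x)))
      as.character(mcols(x)$quality)
    else vapply(width(x), function(w)
      strrep(rawToChar(as.raw(33L + baseQuality)), w), character(1))
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = BStringSet(q))
  }
  invisible(path)
}

#' Read / write a flat key-value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys match the
#' [pipelineConfig()] argument names. Unknown keys are an error.
#'
#' @param path configuration file.
#' @return a [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0L) return(pipelineConfig())
  m <- regmatches(lines, regexec("^([^=]+?)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(m, length, 0L) != 3L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1L]])
  keys <- vapply(m, `[[`, "", 2L)
  vals <- vapply(m, `[[`, "", 3L)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "externalAssemblerCmd") vals[i] else as.numeric(vals[i])
  })
  names(args) <- keys
  do.call(pipelineConfig, args)
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class] to serialise.
#' @export
writePipelineConfig <- function(config, path) {
  keys <- names(formals(pipelineConfig))
  vals <- vapply(keys, function(k) as.character(slot(config, k)), "")
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}

#' Run the full pipeline for one clone
#'
#' Executes de-concatenation, coverage-gated assembly, primary-contig
#' selection, vector trimming/orientation and QC for one clone's reads,
#' optionally writing all intermediates to disk.
#'
#' @param reads a DNAStringSet, or a path to a FASTA/FASTQ file.
#' @param vector a rotated [VectorReference-class].
#' @param config a [PipelineConfig-class].
#' @param cloneId clone identifier.
#' @param outDir optional output directory; when given, writes
#'   `<cloneId>.fragments.fasta`, `<cloneId>.contigs.fasta`,
#'   `<cloneId>.insert.fasta`, `<cloneId>.trim_report.tsv` and
#'   `<cloneId>.log`.
#' @param host optional host genome (character/DNAString) for the
#'   contamination check.
#' @return an [InsertAssembly-class]; its status is `ok` or
#'   `vector_free_contig` on success, `no_assembly_low_coverage` /
#'   `no_assembly_failed` otherwise (low coverage is a status, not an
#'   error).
#' @export
runClone <- function(reads, vector, config = pipelineConfig(),
                     cloneId = "clone", outDir = NULL, host = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readSequences(reads)
  logf <- function(...) {
    if (!is.null(outDir))
      cat(sprintf(...), "\n", sep = "",
          file = file.path(outDir, paste0(cloneId, ".log")), append = TRUE)
  }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  prs <- processReadSet(reads, vector, config)
  logf("%s: %d reads, %d fragments kept, %d bases trimmed", cloneId,
       nrow(prs$report), length(prs$fragments), sum(prs$report$bases_trimmed))
  if (!is.null(outDir)) {
    writeSequences(prs$fragments,
                   file.path(outDir, paste0(cloneId, ".fragments.fasta")))
    utils::write.table(prs$report,
                       file.path(outDir, paste0(cloneId, ".trim_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ao <- assembleFragments(prs$fragments,
                          minInputCoverage = config@minInputCoverage,
                          expectedMoleculeSize = config@expectedMoleculeSize,
                          seed = config@seed, minOverlap = config@minOverlap,
                          minOverlapIdentity = config@minOverlapIdentity,
                          k = config@anchorK, maxGap = config@maxChainGap)
  logf("%s: assembly %s (estimated input coverage %.2fx, %d contig(s))",
       cloneId, ao@status, ao@estimatedInputCoverage, length(contigs(ao)))
  if (ao@status != "assembled")
    return(.insert_assembly(cloneId, "", status = ao@status))
  if (!is.null(outDir)) {
    ct_seqs <- DNAStringSet(vapply(contigs(ao), function(ct)
      as.character(ct@sequence), ""))
    names(ct_seqs) <- vapply(contigs(ao), function(ct)
      sprintf("%s depth=%.1f fragments=%d", ct@contigId, ct@meanDepth,
              ct@nSupportingFragments), "")
    writeSequences(ct_seqs, file.path(outDir, paste0(cloneId, ".contigs.fasta")))
  }

  primary <- selectPrimaryContig(ao)
  ia <- trimContigVector(primary, vector, config, cloneId = cloneId)
  if (!ia@status %in% c("ok", "vector_free_contig")) return(ia)

  qc <- qcReport(prs$fragments, ia@insertSequence,
                 nTotalReads = length(reads), config = config)
  contam <- NA
  if (!is.null(host))
    contam <- checkHostContamination(ia@insertSequence, host, config)$flag
  out <- .insert_assembly(cloneId, as.character(ia@insertSequence),
                          vectorFound = ia@vectorFoundInContig,
                          meanDepth = qc$meanDepth,
                          percentReads = qc$percentReadsContributing,
                          contamination = contam, status = ia@status)
  logf("%s: finished insert %d bp, depth %.1fx, %.1f%% reads contributing",
       cloneId, length(out@insertSequence), out@meanDepth,
       out@percentReadsContributing)
  if (!is.null(outDir)) {
    ins <- DNAStringSet(as.character(out@insertSequence))
    names(ins) <- sprintf("%s length=%d depth=%.1f reads_pct=%.1f contamination=%s",
                          cloneId, length(out@insertSequence), out@meanDepth,
                          out@percentReadsContributing, contam)
    writeSequences(ins, file.path(outDir, paste0(cloneId, ".insert.fasta")))
  }
  out
}

#' Run the pipeline over a manifest of clones
#'
#' Per-clone failures are caught and reported as rows; they never abort the
#' batch.
#'
#' @param manifest a data.frame with columns `clone_id`, `reads_path`, or a
#'   path to a headerless two-column tab-separated file.
#' @param vector a rotated [VectorReference-class].
#' @param config a [PipelineConfig-class].
#' @param outDir optional directory for per-clone outputs and the batch
#'   `summary.tsv`.
#' @param host optional host genome for contamination checks.
#' @return a data.frame with one row per manifest clone: `clone_id`,
#'   `status`, `insert_len`, `mean_depth`, `percent_reads`,
#'   `contamination`.
#' @export
runBatch <- function(manifest, vector, config = pipelineConfig(),
                     outDir = NULL, host = NULL) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, sep = "\t", header = FALSE,
                                  col.names = c("clone_id", "reads_path"),
                                  stringsAsFactors = FALSE)
  }
  stopifnot(all(c("clone_id", "reads_path") %in% names(manifest)))
  if (anyDuplicated(manifest$clone_id))
    stop("duplicate clone ids in manifest: ",
         paste(unique(manifest$clone_id[duplicated(manifest$clone_id)]),
               collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    cid <- manifest$clone_id[i]
    res <- tryCatch(
      runClone(manifest$reads_path[i], vector, config, cloneId = cid,
               outDir = outDir, host = host),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(clone_id = cid, status = "error", insert_len = 0L,
                        mean_depth = 0, percent_reads = 0,
                        contamination = NA, stringsAsFactors = FALSE))
    data.frame(clone_id = cid, status = res@status,
               insert_len = length(res@insertSequence),
               mean_depth = res@meanDepth,
               percent_reads = res@percentReadsContributing,
               contamination = res@contaminationFlag,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(outDir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary
}
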