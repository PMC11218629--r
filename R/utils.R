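# internal helpers shared across modules

.BASES <- c("A", "C", "G", "T")

# evaluate expr under set.seed(seed) without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Random DNA sequence
#'
#' i.i.d.-uniform A/C/G/T string of length `n`, drawn from the current RNG
#' stream.
#'
#' @param n length in bases.
#' @return a character scalar.
#' @export
randomDna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# character-in character-out reverse complement (thin wrapper over the C core)
.revcomp <- function(s) cpp_revcomp(s)

.as_seq_char <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) as.character(x)
  else as.character(x)
}

# empty match table (schema shared with the C++ aligner)
.empty_matches <- function() {
  data.frame(query = integer(0), qstart = integer(0), qend = integer(0),
             rstart = integer(0), rend = integer(0), strand = character(0),
             matches = numeric(0), aln_len = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# total length of the union of 0-based half-open intervals
.interval_union_len <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs)
}
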