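# shared fixtures and independent helpers for the test suite

# independent error injector (deliberately separate from the simulator's)
mutate_seq <- function(s, sub = 0, ins = 0, del = 0) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (del > 0) b <- b[runif(n) >= del]
  n <- length(b)
  if (sub > 0) {
    sm <- which(runif(n) < sub)
    for (i in sm) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  }
  if (ins > 0) {
    out <- character(0)
    im <- runif(n) < ins
    for (i in seq_len(n)) {
      out <- c(out, b[i])
      if (im[i]) out <- c(out, sample(c("A", "C", "G", "T"), 1))
    }
    b <- out
  }
  paste(b, collapse = "")
}

rc_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# small shared stand-in vector (cached across tests)
test_vector <- local({
  v <- NULL
  function() {
    if (is.null(v)) v <<- standInVector()
    v
  }
})

dna_set <- function(seqs, prefix = "read") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("%s_%03d", prefix, seq_along(seqs))
  x
}
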