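test_that("interval merging matches a boolean-mask oracle", {
  m <- mergeVectorIntervals(data.frame(start = c(100, 520), end = c(500, 900)),
                            maxGap = 50)
  expect_equal(m, data.frame(start = 100L, end = 900L))
  m2 <- mergeVectorIntervals(data.frame(start = c(100, 600), end = c(500, 900)),
                             maxGap = 50)
  expect_equal(m2, data.frame(start = c(100L, 600L), end = c(500L, 900L)))
  expect_equal(nrow(mergeVectorIntervals(data.frame(start = integer(0),
                                                    end = integer(0)))), 0L)

  # property: for arbitrary inputs the result equals closing the gaps of a
  # boolean occupancy mask
  set.seed(201)
  for (rep in 1:10) {
    n <- sample(1:10, 1)
    st <- sample(0:500, n)
    en <- st + sample(1:100, n, replace = TRUE)
    gap <- sample(c(0L, 10L, 50L), 1)
    got <- mergeVectorIntervals(data.frame(start = st, end = en), maxGap = gap)
    # oracle: mark covered positions, close runs of uncovered <= gap
    mask <- logical(700)
    for (i in seq_len(n)) mask[(st[i] + 1):en[i]] <- TRUE
    r <- rle(mask)
    idx <- which(!r$values & r$lengths <= gap)
    idx <- idx[idx > 1 & idx < length(r$values)]  # only internal gaps close
    r$values[idx] <- TRUE
    mask <- inverse.rle(r)
    r2 <- rle(mask)
    ends <- cumsum(r2$lengths)
    starts <- ends - r2$lengths
    expect_equal(got$start, starts[r2$values])
    expect_equal(got$end, ends[r2$values])
  }
})

test_that("read trimming keeps exactly the flank complement above the length filter", {
  set.seed(202)
  read <- randomDna(10000)
  fr <- trimRead(read, data.frame(start = 2000, end = 6000), readId = "r1")
  expect_equal(length(fr), 2L)
  md <- S4Vectors::mcols(fr)
  expect_equal(md$src_start, c(0L, 6000L))
  expect_equal(md$src_end, c(2000L, 10000L))
  expect_equal(as.character(fr[[1]]), substr(read, 1, 2000))
  expect_equal(names(fr), c("r1/0", "r1/1"))

  # 100 bp flank is below the 150 nt filter and is discarded
  fr2 <- trimRead(read, data.frame(start = 0, end = 9900))
  expect_equal(length(fr2), 0L)

  # no vector: the whole read is retained as one fragment
  fr3 <- trimRead(read, data.frame(start = integer(0), end = integer(0)))
  expect_equal(length(fr3), 1L)
  expect_equal(S4Vectors::mcols(fr3)$src_start, 0L)
  expect_equal(S4Vectors::mcols(fr3)$src_end, 10000L)

  expect_error(trimRead(read, data.frame(start = c(0, 400), end = c(500, 900))),
               "disjoint")
  expect_error(trimRead(read, data.frame(start = 500, end = 10500)), "bounds")
})

test_that("trimming conserves bases: kept + trimmed + filtered == read length", {
  set.seed(203)
  for (rep in 1:10) {
    L <- sample(2000:8000, 1)
    read <- randomDna(L)
    k <- sample(0:3, 1)
    iv <- if (k == 0) data.frame(start = integer(0), end = integer(0)) else {
      cuts <- sort(sample(0:L, 2 * k))
      data.frame(start = cuts[seq(1, 2 * k, 2)], end = cuts[seq(2, 2 * k, 2)])
    }
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    iv <- mergeVectorIntervals(iv, maxGap = 0)
    fr <- trimRead(read, iv, minFragmentLen = 150)
    trimmed <- sum(iv$end - iv$start)
    # complement pieces, before filtering
    bounds <- c(0, as.vector(rbind(iv$start, iv$end)), L)
    piece_len <- bounds[seq(2, length(bounds), 2)] -
                 bounds[seq(1, length(bounds), 2)]
    filtered <- sum(piece_len[piece_len < 150])
    expect_equal(sum(Biostrings::width(fr)) + trimmed + filtered, L)
  }
})

test_that("raising the fragment filter never increases retained output", {
  set.seed(204)
  read <- randomDna(5000)
  iv <- data.frame(start = c(100, 1500, 4800), end = c(1400, 4600, 4900))
  prev_n <- Inf; prev_b <- Inf
  for (mfl in c(50, 150, 500, 1000)) {
    fr <- trimRead(read, iv, minFragmentLen = mfl)
    expect_lte(length(fr), prev_n)
    expect_lte(sum(Biostrings::width(fr)), prev_b)
    prev_n <- length(fr); prev_b <- sum(Biostrings::width(fr))
  }
})

test_that("processReadSet trims vector passes out of concatemer reads exactly", {
  vec <- test_vector()
  vs <- as.character(vectorSequence(vec))
  set.seed(205)
  # vector-free reads pass through untouched
  free <- dna_set(replicate(20, randomDna(3000)), "free")
  prs <- processReadSet(free, vec)
  expect_equal(length(prs$fragments), 20L)
  expect_equal(sum(prs$report$bases_trimmed), 0L)
  expect_equal(S4Vectors::mcols(prs$fragments)$strand, rep("*", 20))

  # error-free concatemers: flank + vector + flank (+ vector + flank)
  ins <- randomDna(12000)
  reads <- dna_set(c(
    paste0(substr(ins, 1, 2000), vs, substr(ins, 2001, 5000)),
    paste0(substr(ins, 5001, 6000), vs, substr(ins, 6001, 9000), vs,
           substr(ins, 9001, 12000))), "cat")
  prs2 <- processReadSet(reads, vec)
  total_read <- sum(Biostrings::width(reads))
  total_vector <- 3L * nchar(vs)
  expect_equal(sum(Biostrings::width(prs2$fragments)),
               total_read - total_vector)
  expect_equal(prs2$report$n_fragments_kept, c(2L, 3L))
  expect_equal(prs2$report$bases_trimmed, c(nchar(vs), 2L * nchar(vs)))

  # pure vector reads leave nothing
  prs3 <- processReadSet(dna_set(c(vs, vs), "pure"), vec)
  expect_equal(length(prs3$fragments), 0L)

  # idempotence: re-running on the fragments trims zero additional bases
  prs4 <- processReadSet(prs2$fragments, vec)
  expect_equal(sum(prs4$report$bases_trimmed), 0L)
  expect_equal(sum(Biostrings::width(prs4$fragments)),
               sum(Biostrings::width(prs2$fragments)))
})

test_that("fragments from minus-strand reads are flipped to template orientation", {
  vec <- test_vector()
  vs <- as.character(vectorSequence(vec))
  set.seed(206)
  flank <- randomDna(2000)
  fwd <- paste0(vs, flank)
  reads <- dna_set(c(fwd, rc_chr(fwd)), "strand")
  prs <- processReadSet(reads, vec)
  expect_equal(length(prs$fragments), 2L)
  expect_equal(S4Vectors::mcols(prs$fragments)$strand, c("+", "-"))
  # both fragments come out in template orientation
  expect_equal(as.character(prs$fragments[[1]]), flank)
  expect_equal(as.character(prs$fragments[[2]]), flank)
})
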