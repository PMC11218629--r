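test_that("exact substrings and their reverse complements are found exactly", {
  set.seed(101)
  ref <- randomDna(2000)
  q <- substr(ref, 101, 600)  # reference[100, 600) in 0-based terms
  m <- findLocalMatches(q, ref, minMatchLen = 100, minIdentity = 85)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "+")
  expect_equal(m$identity, 100)
  expect_equal(c(m$qstart, m$qend), c(0L, 500L))
  expect_equal(c(m$rstart, m$rend), c(100L, 600L))

  m2 <- findLocalMatches(rc_chr(q), ref, minMatchLen = 100, minIdentity = 85)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$strand, "-")
  expect_equal(m2$identity, 100)
  expect_equal(c(m2$rstart, m2$rend), c(100L, 600L))

  # query shorter than the anchor size: silently empty
  expect_equal(nrow(findLocalMatches("ACGTACGT", ref)), 0L)
})

test_that("two substitutions in a 200 bp match give identity 99.0", {
  set.seed(102)
  ref <- randomDna(2000)
  q <- substr(ref, 1, 200)
  substr(q, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(q, 50, 50))[1]
  substr(q, 150, 150) <- setdiff(c("A", "C", "G", "T"), substr(q, 150, 150))[1]
  m <- findLocalMatches(q, ref, minMatchLen = 100, minIdentity = 85)
  expect_equal(nrow(m), 1L)
  expect_equal(m$identity, 99.0)
  expect_equal(m$matches, 198)
  expect_equal(m$aln_len, 200)
})

test_that("the native aligner agrees with a full dynamic-programming oracle", {
  # oracle: Biostrings local pairwise alignment under the same scoring
  set.seed(103)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:5) {
    ref <- randomDna(2000)
    span <- sort(sample(seq_len(2000), 2))
    while (diff(span) < 400) span <- sort(sample(seq_len(2000), 2))
    q <- mutate_seq(substr(ref, span[1], span[2]),
                    sub = 0.01, ins = 0.005, del = 0.005)
    m <- findLocalMatches(q, ref, minMatchLen = 100, minIdentity = 80)
    expect_gte(nrow(m), 1L)
    m <- m[which.max(m$matches), ]
    p <- Biostrings::pairwiseAlignment(q, ref, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
    # same intervals within +-5 bp, identity within +-0.5 points
    expect_lte(abs(m$qstart - (Biostrings::start(Biostrings::pattern(p)) - 1)), 5)
    expect_lte(abs(m$qend - Biostrings::end(Biostrings::pattern(p))), 5)
    expect_lte(abs(m$rstart - (Biostrings::start(Biostrings::subject(p)) - 1)), 5)
    expect_lte(abs(m$rend - Biostrings::end(Biostrings::subject(p))), 5)
    expect_lte(abs(m$identity - Biostrings::pid(p, "PID1")), 0.5)
  }
})

test_that("matches are strand-symmetric", {
  set.seed(104)
  for (i in 1:4) {
    ref <- randomDna(2000)
    q <- mutate_seq(substr(ref, 501, 1500), sub = 0.01)
    mf <- findLocalMatches(q, ref, minMatchLen = 100)
    mr <- findLocalMatches(rc_chr(q), ref, minMatchLen = 100)
    expect_equal(nrow(mf), nrow(mr))
    mf <- mf[order(mf$rstart), ]; mr <- mr[order(mr$rstart), ]
    expect_equal(mf$rstart, mr$rstart)
    expect_equal(mf$rend, mr$rend)
    expect_equal(mf$matches, mr$matches)
    # query coordinates mirror: [qs, qe) -> [L - qe, L - qs)
    expect_equal(mr$qstart, nchar(q) - mf$qend)
    expect_equal(mr$qend, nchar(q) - mf$qstart)
    expect_true(all(mf$strand != mr$strand))
  }
})

test_that("mapFragments produces correct depth profiles", {
  set.seed(105)
  target <- randomDna(1000)
  # non-overlapping tiling partition: depth exactly 1 everywhere
  starts <- seq(1, 1000, by = 250)
  frs <- dna_set(substring(target, starts, starts + 249))
  mp <- mapFragments(frs, target)
  expect_equal(mp$depth, rep(1L, 1000))
  expect_true(all(mp$mapped))

  # empty input: all-zero profile
  mp0 <- mapFragments(Biostrings::DNAStringSet(), target)
  expect_equal(mp0$depth, rep(0L, 1000))
  expect_equal(mp0$meanDepth, 0)

  # ten full-span error-free fragments: uniform depth 10, mean exactly 10
  frs10 <- dna_set(rep(target, 10))
  mp10 <- mapFragments(frs10, target)
  expect_equal(mp10$depth, rep(10L, 1000))
  expect_equal(mp10$meanDepth, 10.0)
})

test_that("PAF export/import round-trips the match table", {
  set.seed(106)
  ref <- randomDna(1500)
  qs <- dna_set(c(substr(ref, 101, 700), rc_chr(substr(ref, 801, 1400))))
  m <- findLocalMatches(qs, ref)
  paf <- matchesToPaf(m, names(qs), Biostrings::width(qs), "ref", nchar(ref))
  expect_equal(length(paf), nrow(m))
  back <- pafToMatches(paf, queryNames = names(qs))
  expect_equal(back$qstart, m$qstart)
  expect_equal(back$qend, m$qend)
  expect_equal(back$rstart, m$rstart)
  expect_equal(back$strand, m$strand)
  expect_equal(back$query, m$query)
  expect_error(pafToMatches("only\tthree\tfields"), "malformed PAF")
})
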