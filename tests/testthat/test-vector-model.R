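test_that("rotation puts the MCS at the 3' end and is a circular permutation", {
  rv <- rotateVector("AAACCCGGGTTT", c(3, 6))
  expect_equal(as.character(vectorSequence(rv)), "GGGTTTAAACCC")
  expect_equal(mcsInterval(rv), c(9L, 12L))
  expect_true(isRotated(rv))

  # MCS already terminal: identity
  rv2 <- rotateVector("AAACCCGGGTTT", c(9, 12))
  expect_equal(as.character(vectorSequence(rv2)), "AAACCCGGGTTT")
  expect_true(isRotated(rv2))

  # single-base MCS at the start
  rv3 <- rotateVector("GATTACA", c(0, 1))
  expect_equal(as.character(vectorSequence(rv3)), "ATTACAG")
  expect_equal(mcsInterval(rv3), c(6L, 7L))

  # property: rotation preserves the circle (doubled original contains it)
  set.seed(42)
  for (i in 1:10) {
    s <- randomDna(sample(50:200, 1))
    st <- sample(0:(nchar(s) - 2), 1)
    en <- sample((st + 1):nchar(s), 1)
    rot <- as.character(vectorSequence(rotateVector(s, c(st, en))))
    expect_equal(nchar(rot), nchar(s))
    expect_true(grepl(rot, paste0(s, s), fixed = TRUE))
  }
})

test_that("rotation rejects bad intervals and non-DNA input", {
  expect_error(rotateVector("ACGT", c(2, 7)), "out of bounds")
  expect_error(rotateVector("ACGT", c(-1, 2)), "out of bounds")
  expect_error(rotateVector("ACXT", c(0, 2)), "A,C,G,T,N")
})

test_that("digestion yields the expected fragment multisets", {
  enz <- commonEnzymes()
  # 16-mer circle: SacI cut at 5, XhoI cut at 11 -> fragments 6 and 10
  expect_equal(digestSequence("GAGCTCAAAACTCGAG", "circular", enz),
               c(10L, 6L))
  # uncut circle -> one full-length fragment
  expect_equal(digestSequence("AAAATTTTCCCC", "circular", list()), 12L)
  # linear with one SacI site at offset 2: cut at 7 -> 7 and 3
  expect_equal(digestSequence("AAGAGCTCAA", "linear", enz[1]), c(7L, 3L))
})

test_that("digestion conserves molecule length against a brute-force site scan", {
  enz <- commonEnzymes()
  set.seed(11)
  for (i in 1:12) {
    # random backbone with some planted sites
    s <- randomDna(300)
    for (site in c("GAGCTC", "CTCGAG"))
      for (p in sample(1:280, sample(0:3, 1)))
        substr(s, p, p + 5) <- site
    for (topo in c("circular", "linear")) {
      frags <- digestSequence(s, topo, enz)
      expect_equal(sum(frags), nchar(s))
      # brute-force oracle: scan every rotation-free position for a site
      cuts <- integer(0)
      scan <- if (topo == "circular") paste0(s, substr(s, 1, 5)) else s
      for (e in enz) {
        for (p in seq_len(nchar(scan) - 5)) {
          if (substr(scan, p, p + 5) == e@recognition && p <= nchar(s)) {
            cut <- p - 1 + e@cutOffset
            cuts <- c(cuts, if (topo == "circular") cut %% nchar(s) else cut)
          }
        }
      }
      cuts <- sort(unique(cuts[cuts <= nchar(s)]))
      expected_n <- if (topo == "circular") max(1L, length(cuts))
                    else length(cuts[cuts > 0 & cuts < nchar(s)]) + 1L
      expect_equal(length(frags), expected_n)
    }
  }
})

test_that("packaged pCC1 primers have lengths 27 and 26", {
  pr <- pcc1Primers()
  expect_equal(nchar(pr@forward), 27L)
  expect_equal(nchar(pr@reverse), 26L)
})

test_that("the synthetic stand-in vector is deterministic and well-formed", {
  v1 <- standInVector()
  v2 <- standInVector()
  expect_equal(as.character(vectorSequence(v1)), as.character(vectorSequence(v2)))
  expect_true(isRotated(v1))
  expect_equal(mcsInterval(v1)[2], length(vectorSequence(v1)))
  s <- as.character(vectorSequence(v1))
  expect_equal(length(gregexpr("GAGCTC", s, fixed = TRUE)[[1]]), 1L)
  expect_equal(length(gregexpr("CTCGAG", s, fixed = TRUE)[[1]]), 1L)
  # carries the backbone primer sites
  expect_true(grepl(pcc1Primers()@forward, s, fixed = TRUE))
})

test_that("enzyme and vector validity rules are enforced", {
  expect_error(restrictionEnzyme("bad", "GAGCTC", 7L), "cutOffset")
  expect_error(vectorReference("v", "ACGT", 2, 6), "within")
  expect_error(vectorReference("v", "", 0, 1), "non-empty")
})
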