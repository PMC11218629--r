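test_that("internal vector is trimmed and flanks re-joined in MCS order", {
  vec <- test_vector()
  vs <- as.character(vectorSequence(vec))
  set.seed(401)
  A <- randomDna(3000)  # insert start (downstream of the MCS)
  B <- randomDna(2000)  # insert end
  # contig linearised mid-insert: end-of-insert, vector, start-of-insert
  ctg <- contig("tigA", paste0(B, vs, A), 10, 5L)
  ia <- trimContigVector(ctg, vec)
  expect_equal(assemblyStatus(ia), "ok")
  expect_true(vectorFoundInContig(ia))
  expect_equal(as.character(insertSequence(ia)), paste0(A, B))

  # minus-strand contig is reverse-complemented before trimming
  ctg2 <- contig("tigB", rc_chr(paste0(B, vs, A)), 10, 5L)
  ia2 <- trimContigVector(ctg2, vec)
  expect_equal(as.character(insertSequence(ia2)), paste0(A, B))

  # terminal vector: single flank, trim only
  ctg3 <- contig("tigC", paste0(vs, A), 10, 5L)
  ia3 <- trimContigVector(ctg3, vec)
  expect_equal(as.character(insertSequence(ia3)), A)

  # no vector similarity: unchanged, status vector_free_contig
  ctg4 <- contig("tigD", paste0(A, B), 10, 5L)
  ia4 <- trimContigVector(ctg4, vec)
  expect_equal(assemblyStatus(ia4), "vector_free_contig")
  expect_false(vectorFoundInContig(ia4))
  expect_equal(as.character(insertSequence(ia4)), paste0(A, B))
})

test_that("flanks overlapping across more than one circle are merged by consensus", {
  vec <- test_vector()
  vs <- as.character(vectorSequence(vec))
  set.seed(402)
  ins <- randomDna(12000)
  # contig walks > 1 full circle: 3 kb of insert end, vector, 9.5 kb from
  # the insert start -> flanks share a 500 bp overlap
  ctg <- contig("tigE", paste0(substr(ins, 9001, 12000), vs,
                               substr(ins, 1, 9500)), 10, 5L)
  ia <- trimContigVector(ctg, vec)
  expect_equal(as.character(insertSequence(ia)), ins)
})

test_that("vector removal from the finished insert is idempotent", {
  vec <- test_vector()
  vs <- as.character(vectorSequence(vec))
  set.seed(403)
  ctg <- contig("tigF", paste0(randomDna(2500), vs, randomDna(2500)), 10, 5L)
  ia <- trimContigVector(ctg, vec)
  cfg <- pipelineConfig()
  m <- findLocalMatches(as.character(insertSequence(ia)),
                        vs, minMatchLen = cfg@minMatchLen,
                        minIdentity = cfg@minMatchIdentity)
  expect_equal(nrow(m), 0L)
})

test_that("more than two vector blocks warn and trim everything", {
  vec <- test_vector()
  vs <- as.character(vectorSequence(vec))
  set.seed(404)
  parts <- replicate(4, randomDna(1000))
  ctg <- contig("tigG", paste0(parts[1], vs, parts[2], vs, parts[3], vs,
                               parts[4]), 10, 5L)
  expect_warning(ia <- trimContigVector(ctg, vec), "double-backbone")
  expect_equal(as.character(insertSequence(ia)),
               paste0(parts[2], parts[3], parts[4], parts[1]))
})

test_that("the host-contamination rule is strict at both thresholds", {
  expect_true(flagHostContamination(96, 92))
  expect_false(flagHostContamination(95, 92))
  expect_false(flagHostContamination(96, 90))
  expect_false(flagHostContamination(95, 90))
  expect_error(flagHostContamination(101, 50))
})

test_that("host contamination is detected by alignment against the host genome", {
  set.seed(405)
  host <- randomDna(20000)
  embedded <- substr(host, 5001, 9000)     # contig lifted from the host
  unrelated <- randomDna(4000)
  r1 <- checkHostContamination(embedded, host)
  expect_true(r1$flag)
  expect_gt(r1$identity, 99)
  r2 <- checkHostContamination(unrelated, host)
  expect_false(r2$flag)
})

test_that("QC metrics follow the mapping definitions", {
  set.seed(406)
  ins <- randomDna(1000)
  # ten full-span fragments from ten distinct reads out of ten
  frs <- dna_set(rep(ins, 10))
  S4Vectors::mcols(frs) <- S4Vectors::DataFrame(
    parent_id = sprintf("r%02d", 1:10))
  qc <- qcReport(frs, ins, nTotalReads = 10)
  expect_equal(qc$meanDepth, 10)
  expect_equal(qc$percentReadsContributing, 100)

  # five half-covering fragments from five reads out of ten
  frs2 <- dna_set(rep(substr(ins, 1, 500), 5))
  S4Vectors::mcols(frs2) <- S4Vectors::DataFrame(
    parent_id = sprintf("r%02d", 1:5))
  qc2 <- qcReport(frs2, ins, nTotalReads = 10)
  expect_equal(qc2$meanDepth, 2.5)
  expect_equal(qc2$percentReadsContributing, 50)

  expect_equal(qcReport(Biostrings::DNAStringSet(), ins),
               list(meanDepth = 0, percentReadsContributing = 0))
})
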