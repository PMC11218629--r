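test_that("simulated fosmids have the right structure and are deterministic", {
  vec <- test_vector()
  f1 <- makeFosmid(vec, 32000, seed = 7)
  expect_equal(circumference(f1), length(vectorSequence(vec)) + 32000L)
  expect_equal(as.character(fosmidCircle(f1)),
               paste0(as.character(vectorSequence(vec)),
                      as.character(fosmidInsert(f1))))
  f2 <- makeFosmid(vec, 32000, seed = 7)
  expect_identical(as.character(fosmidCircle(f1)), as.character(fosmidCircle(f2)))
  f3 <- makeFosmid(vec, 32000, seed = 8)
  expect_false(identical(as.character(fosmidInsert(f1)),
                         as.character(fosmidInsert(f3))))
  # i.i.d.-uniform insert: GC fraction tightly around 0.5 at n = 30,000
  ins <- strsplit(as.character(fosmidInsert(makeFosmid(vec, 30000, seed = 9))),
                  "")[[1]]
  gc <- mean(ins %in% c("G", "C"))
  expect_gt(gc, 0.48); expect_lt(gc, 0.52)
})

test_that("rolling-circle reads wrap the circular template", {
  set.seed(501)
  circle <- randomDna(1000)
  r <- rcaReadFromCircle(circle, start = 800, strand = "+", length = 500)
  expect_equal(r$sequence, paste0(substr(circle, 801, 1000),
                                  substr(circle, 1, 300)))
  expect_equal(r$truth$end, 1300)
  rm <- rcaReadFromCircle(circle, start = 800, strand = "-", length = 500)
  expect_equal(rm$sequence, rc_chr(r$sequence))
})

test_that("error-free truth segments reconstruct each read exactly", {
  vec <- test_vector()
  fos <- makeFosmid(vec, 6000, seed = 10)
  cfg <- simulationConfig(seed = 11, nReads = 20, readLengthMedian = 8000,
                          substitutionRate = 0, insertionRate = 0,
                          deletionRate = 0, chimeraRate = 0)
  sim <- simulateRcaReads(fos, cfg)
  circle <- as.character(fosmidCircle(fos))
  for (i in seq_along(sim$reads)) {
    segs <- sim$truth[sim$truth$read_id == names(sim$reads)[i], ]
    segs <- segs[order(segs$segment), ]
    rebuilt <- paste(vapply(seq_len(nrow(segs)), function(j) {
      r <- rcaReadFromCircle(circle, segs$start[j], segs$strand[j],
                             segs$end[j] - segs$start[j])
      r$sequence
    }, ""), collapse = "")
    expect_equal(as.character(sim$reads[[i]]), rebuilt)
  }
})

test_that("reads longer than the circumference span complete vector copies", {
  vec <- test_vector()
  fos <- makeFosmid(vec, 32000, seed = 12)  # 40 kb circle
  cfg <- simulationConfig(seed = 13, nReads = 5, readLengthMedian = 100000,
                          readLengthSdLog = 0.01, substitutionRate = 0,
                          insertionRate = 0, deletionRate = 0, chimeraRate = 0)
  sim <- simulateRcaReads(fos, cfg)
  # 100 kb reads walk ~2.5 circuits: at least 2 full vector copies
  expect_true(all(sim$summary$n_vector_copies >= 2))
  # and the vector sequence literally occurs that many times in the read
  vs <- as.character(vectorSequence(vec))
  r1 <- as.character(sim$reads[[1]])
  if (sim$truth$strand[sim$truth$read_id == names(sim$reads)[1]][1] == "-")
    r1 <- rc_chr(r1)
  n_occ <- length(gregexpr(vs, r1, fixed = TRUE)[[1]])
  expect_equal(n_occ, sim$summary$n_vector_copies[1])
})

test_that("simulation is deterministic and read lengths match the configuration", {
  vec <- test_vector()
  fos <- makeFosmid(vec, 6000, seed = 14)
  cfg <- simulationConfig(seed = 15, nReads = 400, readLengthMedian = 11500)
  s1 <- simulateRcaReads(fos, cfg)
  s2 <- simulateRcaReads(fos, cfg)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(S4Vectors::mcols(s1$reads)$quality,
                   S4Vectors::mcols(s2$reads)$quality)
  expect_identical(s1$truth, s2$truth)
  # empirical median within 10% of the configured median at n = 400
  med <- stats::median(Biostrings::width(s1$reads))
  expect_gt(med, 11500 * 0.9); expect_lt(med, 11500 * 1.1)
  # qualities are constant and as long as the read
  expect_equal(nchar(S4Vectors::mcols(s1$reads)$quality[1]),
               Biostrings::width(s1$reads)[1])
})

test_that("chimeric reads carry a junction and truth marks it", {
  vec <- test_vector()
  fos <- makeFosmid(vec, 6000, seed = 16)
  cfg <- simulationConfig(seed = 17, nReads = 60, readLengthMedian = 6000,
                          substitutionRate = 0, insertionRate = 0,
                          deletionRate = 0, chimeraRate = 1,
                          invertedChimeraFraction = 0.5)
  sim <- simulateRcaReads(fos, cfg)
  expect_true(all(sim$summary$n_segments == 2))
  j <- sim$truth[sim$truth$segment == 0, ]
  expect_true(all(j$chimeric_junction_after))
  # about half the junctions invert the strand
  s0 <- sim$truth$strand[sim$truth$segment == 0]
  s1 <- sim$truth$strand[sim$truth$segment == 1]
  inv <- mean(s0 != s1)
  expect_gt(inv, 0.25); expect_lt(inv, 0.75)
})

test_that("insert evaluation reports identity, truth coverage and length delta", {
  vec <- test_vector()
  fos <- makeFosmid(vec, 30000, seed = 18)
  truth <- as.character(fosmidInsert(fos))
  ev <- evaluateAgainstTruth(truth, fos)
  expect_equal(ev$identity, 100)
  expect_equal(ev$coverage_of_truth, 100)
  expect_equal(ev$length_delta, 0L)
  # missing the last 300 bp of a 30 kb truth: coverage 99
  ev2 <- evaluateAgainstTruth(substr(truth, 1, 29700), fos)
  expect_equal(ev2$coverage_of_truth, 99.0)
  expect_equal(ev2$length_delta, -300L)
})
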