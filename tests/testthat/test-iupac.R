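test_that("sequence normalization uppercases, maps T to U, and keeps a case mask", {
  ns <- normalize_sequence("uCUCA")
  expect_equal(ns$sequence, "UCUCA")
  expect_equal(ns$lowercase, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(normalize_sequence("acgt")$sequence, "ACGU")
  expect_error(normalize_sequence("ACGX"), "position 4")
  expect_error(normalize_sequence(""), "non-empty")
})

test_that("fragment extraction follows the capitals convention", {
  r <- extract_fragment("UUGACAGAAGAUAGAGAGCAc", 20)
  expect_equal(r$fragment, "UUGACAGAAGAUAGAGAGCA")
  expect_equal(r$fragment_offset, 1L)
  r2 <- extract_fragment("aAUGACACGAUCACUCCCGUUGA", 22)
  expect_equal(r2$fragment_offset, 2L)
  expect_equal(nchar(r2$fragment), 22L)
  # internal uppercase run, lowercase on both flanks
  r3 <- extract_fragment("ugaUUGAAGAGGACUcc", 12)
  expect_equal(r3$fragment_offset, 4L)
  expect_equal(r3$fragment, "UUGAAGAGGACU")
  expect_error(extract_fragment("ACGUACGUAC", 20), "shorter")
  expect_warning(extract_fragment(strrep("ACGU", 6), 20), "leading")
})

test_that("degenerate expansion sizes and contents are correct", {
  expect_length(expand_degenerate("NNNN"), 256)
  expect_equal(expand_degenerate("AUGC"), "AUGC")
  expect_length(expand_degenerate("RHHK"), 2 * 3 * 3 * 2)
  expect_true(all(grepl("^[ACGU]{4}$", expand_degenerate("WSBV"))))
  expect_error(expand_degenerate("AXGU"), "invalid IUPAC")
  expect_error(expand_degenerate("AUG"), "exactly 4")
})

test_that("window matching agrees with set expansion on random cases", {
  expect_true(tetra_matches("AGAA", "WRHW"))
  expect_false(tetra_matches("UGAC", "WRHW"))
  set.seed(11)
  for (k in 1:1000) {
    w <- random_fragment(4)
    t <- random_tetra()
    expect_identical(tetra_matches(w, t), w %in% expand_degenerate(t))
  }
})

test_that("total expansion mass over all 50625 patterns is 32^4", {
  sizes <- degeneracy(tetra_space())
  expect_length(sizes, 15^4)
  expect_equal(sum(sizes), 32^4)
})

test_that("sigma/delta is an exact bijection and matches the printed pairs", {
  sd1 <- sigma_delta(7.81, 4.85)
  expect_equal(sd1$sigma, 6.33)
  expect_equal(sd1$delta, 1.48)
  expect_equal(sigma_delta(5.28, 7.98)$delta, -1.35)
  expect_equal(sigma_delta(3.3, 3.3)$delta, 0)
  set.seed(2)
  x2 <- rnorm(50); x3 <- rnorm(50)
  sd2 <- sigma_delta(x2, x3)
  expect_equal(sd2$sigma + sd2$delta, x2)
  expect_equal(sd2$sigma - sd2$delta, x3)
})

test_that("FASTA and activity TSV round-trips are the identity", {
  ids <- c("mir-a", "mir-b", "mir-c")
  seqs <- c("uGACAGAAGAGAGUGAGCACAa", "UCCCAAAUGUAGACAAAGCA", "ACGUACGUACGUACGUACGU")
  fa <- tempfile(fileext = ".fa")
  write_fasta(ids, seqs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, ids)
  expect_equal(back$sequence, seqs)

  ds <- suppressWarnings(activity_dataset(ids, seqs, c(3.09, -1.25, 0.123456),
                                          fragment_length = 20))
  tsv <- tempfile(fileext = ".tsv")
  write_activity_tsv(ds, tsv)
  ds2 <- suppressWarnings(read_activity_tsv(tsv, fragment_length = 20))
  expect_equal(ds2$id, ds$id)
  expect_equal(ds2$raw, ds$raw)
  expect_equal(ds2$activity, ds$activity, tolerance = 1e-6)
})

test_that("activity TSV parsing reports malformed input precisely", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tactivity",
               "a\tACGUACGUAC\t1.5",
               "b\tACGUACGUAC\tn/a"), tsv)
  expect_error(suppressWarnings(read_activity_tsv(tsv, fragment_length = 8)),
               "row 2")
  writeLines(c("id\tsequence\tactivity",
               "a\tACGUACGUAC\t1.5",
               "a\tACGUACGUAC\t2.5"), tsv)
  expect_error(suppressWarnings(read_activity_tsv(tsv, fragment_length = 8)),
               "duplicate")
})

test_that("packaged training tables load with their published annotations", {
  t1 <- load_table1()
  expect_length(t1, 17)
  expect_equal(t1$fragment_length, 20L)
  expect_true(all(nchar(t1$fragment) == 20))
  expect_equal(t1$fragment[1], "UGACAGAAGAGAGUGAGCAC")
  expect_equal(t1$activity[1], 3.09)

  t2 <- load_table2()
  expect_length(t2, 12)
  expect_equal(t2$fragment_length, 22L)
  expect_equal(t2$extra$x2[1], 7.81)
  expect_equal(t2$fragment_offset[1], 2L)  # leading lowercase u trimmed
  # the annotated sigma/delta columns obey the half-sum/half-difference
  # identities with the raw affinities at table precision
  sd <- sigma_delta(t2$extra$x2, t2$extra$x3)
  expect_lte(max(abs(sd$sigma - t2$extra$sigma)), 0.0051)
  expect_lte(max(abs(sd$delta - t2$extra$delta)), 0.0051)
})
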