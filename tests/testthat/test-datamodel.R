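test_that("read_cohort records empty cells and zeros as missing", {
  paths <- write_toy_cohort_files()
  d <- read_cohort(paths$abundance, paths$metadata, paths$annotations)
  expect_s3_class(d, "cohort_dataset")
  expect_equal(sum(missing_mask(d)), 1L)
  expect_true(is.na(d$abundance["S2", "C1"]))

  paths0 <- write_toy_cohort_files(abundance_lines = c(
    "compound_id,S1,S2,S3", "C1,4.0,0,9.0", "C2,1.5,2.5,3.5"))
  d0 <- read_cohort(paths0$abundance, paths0$metadata, paths0$annotations)
  expect_true(is.na(d0$abundance["S2", "C1"]))
  expect_equal(sum(missing_mask(d0)), 1L)
})

test_that("read_cohort validation names the offending entity", {
  paths <- write_toy_cohort_files(abundance_lines = c(
    "compound_id,S1,S2,S9", "C1,4.0,5.0,9.0", "C2,1.5,2.5,3.5"))
  expect_error(
    read_cohort(paths$abundance, paths$metadata, paths$annotations), "S9")

  paths2 <- write_toy_cohort_files(abundance_lines = c(
    "compound_id,S1,S2,S3", "C1,4.0,oops,9.0", "C2,1.5,2.5,3.5"))
  expect_error(
    read_cohort(paths2$abundance, paths2$metadata, paths2$annotations),
    "non-numeric.*oops")
})

test_that("cohort_dataset enforces its invariants", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(make_cohort(m, groups = c(1, 2)), "0.*1|coded")
  expect_error(make_cohort(m, groups = c(1, 0),
                           inchikey = c("BROKENKEY", NA)), "InChIKey")
  expect_silent(make_cohort(m, groups = c(1, 0),
                            inchikey = c("QNAYBMKLOCPYGJ-REOHCLBHSA-N", NA)))
  m2 <- m; m2[1, 1] <- -1
  expect_error(make_cohort(m2, groups = c(1, 0)), "positive")
})

test_that("match_compounds pairs by InChIKey with exact set semantics", {
  keys_a <- c("AAAAAAAAAAAAAA-AAAAAAAAAA-A", "BBBBBBBBBBBBBB-BBBBBBBBBB-B",
              "CCCCCCCCCCCCCC-CCCCCCCCCC-C")
  keys_b <- c(keys_a[2:3], "DDDDDDDDDDDDDD-DDDDDDDDDD-D")
  a <- make_cohort(matrix(1:6, 2, 3), c(1, 0), ids = c("a1", "a2", "a3"),
                   inchikey = keys_a)
  b <- make_cohort(matrix(1:6, 2, 3), c(1, 0), ids = c("b1", "b2", "b3"),
                   inchikey = keys_b)
  mt <- match_compounds(a, b)
  expect_equal(nrow(mt$pairs), 2L)
  expect_setequal(mt$unmatched_a, "a1")
  expect_setequal(mt$unmatched_b, "b3")

  # identity: a dataset matched to itself pairs every keyed compound
  self <- match_compounds(a, a)
  expect_equal(nrow(self$pairs), 3L)
  expect_equal(self$pairs$compound_id_a, self$pairs$compound_id_b)

  # duplicated key within one dataset is ambiguous
  dup <- make_cohort(matrix(1:4, 2, 2), c(1, 0), ids = c("d1", "d2"),
                     inchikey = rep(keys_a[1], 2))
  expect_error(match_compounds(dup, b), "ambiguous")
})

test_that("match_compounds is symmetric and bounded", {
  set.seed(33)
  pool <- replicate(12, paste0(
    paste(sample(LETTERS, 14, TRUE), collapse = ""), "-",
    paste(sample(LETTERS, 10, TRUE), collapse = ""), "-",
    sample(LETTERS, 1)))
  for (i in 1:5) {
    ka <- sample(pool, 6)
    kb <- sample(pool, 7)
    a <- make_cohort(matrix(seq_len(2 * 6), 2), c(1, 0),
                     ids = paste0("a", 1:6), inchikey = ka)
    b <- make_cohort(matrix(seq_len(2 * 7), 2), c(1, 0),
                     ids = paste0("b", 1:7), inchikey = kb)
    ab <- match_compounds(a, b)$pairs
    ba <- match_compounds(b, a)$pairs
    expect_lte(nrow(ab), min(6, 7))
    expect_setequal(paste(ab$compound_id_a, ab$compound_id_b),
                    paste(ba$compound_id_b, ba$compound_id_a))
  }
})

test_that("match_compounds accepts a user-supplied mapping table", {
  a <- make_cohort(matrix(1:4, 2, 2), c(1, 0), ids = c("a1", "a2"))
  b <- make_cohort(matrix(1:4, 2, 2), c(1, 0), ids = c("b1", "b2"))
  mt <- match_compounds(a, b, key = "mapping",
                        mapping = data.frame(from = "a2", to = "b1"))
  expect_equal(mt$pairs$compound_id_a, "a2")
  expect_equal(mt$pairs$compound_id_b, "b1")
})

test_that("a cohort round-trips through the three tables exactly", {
  set.seed(71)
  m <- matrix(exp(rnorm(40, 2)), 8, 5)
  m[cbind(sample(8, 6, TRUE), sample(5, 6, TRUE))] <- NA
  d <- make_cohort(m, rep(c(1, 0), 4),
                   inchikey = c("QNAYBMKLOCPYGJ-REOHCLBHSA-N",
                                rep(NA, 4)),
                   chem_class = c("AA", "AA", NA, "TG", "TG"))
  dir <- tempfile("roundtrip")
  write_cohort(d, dir)
  back <- read_cohort(file.path(dir, "abundance.tsv"),
                      file.path(dir, "metadata.tsv"),
                      file.path(dir, "annotations.tsv"))
  expect_equal(back$abundance, d$abundance, tolerance = 0)
  expect_identical(missing_mask(back), missing_mask(d))
  expect_equal(back$compounds$inchikey, d$compounds$inchikey)
  expect_equal(back$samples$group, d$samples$group)
})

test_that("result tables round-trip through TSV at full precision", {
  tbl <- data.frame(compound_id = paste0("C", 1:5),
                    value = c(pi, exp(1), 1 / 3, 1.23456789012345e-7, 42),
                    flag = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_results(tbl, path)
  lines <- readLines(path)
  expect_length(lines, 6L)            # header + 5 rows
  back <- read_results(path)
  expect_equal(back$value, tbl$value, tolerance = 1e-12)
  expect_equal(back$compound_id, tbl$compound_id)

  expect_error(write_results(tbl[0, ], tempfile()), "empty")
})
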