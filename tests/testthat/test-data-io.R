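test_that("expression matrix survives a write-read round trip", {
  m <- randomMatrix(20, 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, path)
  m2 <- suppressMessages(readExpressionMatrix(path, platform = "test"))
  expect_equal(probeIds(m2), probeIds(m))
  expect_equal(sampleIds(m2), sampleIds(m))
  expect_equal(exprValues(m2), exprValues(m), tolerance = 1e-12)
  expect_identical(platformLabel(m2), "test")

  # smallest valid input
  tiny <- ExpressionMatrix(matrix(1:4 + 0.5, 2, 2,
                                  dimnames = list(c("a_at", "b_at"),
                                                  c("s1", "s2"))))
  writeExpressionMatrix(tiny, path)
  expect_equal(dim(suppressMessages(readExpressionMatrix(path))), c(2L, 2L))
})

test_that("a platform-sized file reads back with every probe row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  vals <- matrix(round(rnorm(22283 * 2, 500, 120), 3), 22283, 2,
                 dimnames = list(sprintf("%05d_at", seq_len(22283)),
                                 c("s1", "s2")))
  writeExpressionMatrix(ExpressionMatrix(vals), path)
  m <- suppressMessages(readExpressionMatrix(path, platform = "A-AFFY-33"))
  expect_equal(length(probeIds(m)), 22283L)
})

test_that("malformed matrices are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "X_at\t1\t2", "X_at\t3\t4"), path)
  expect_error(readExpressionMatrix(path), "X_at")

  writeLines(c("probe_id\ts1\ts2", "A_at\t1\toops"), path)
  err <- tryCatch(readExpressionMatrix(path), error = conditionMessage)
  expect_match(err, "oops")
  expect_match(err, "A_at")
  expect_match(err, "s2")

  file.create(path2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_error(readExpressionMatrix(path2), "empty")
})

test_that("missing cells are rejected by default and median-imputable", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2\ts3", "A_at\t1\t\t3", "B_at\t4\t5\t6"), path)
  expect_error(readExpressionMatrix(path), "missing")
  m <- suppressMessages(readExpressionMatrix(path, impute = "median"))
  expect_equal(unname(exprValues(m)["A_at", "s2"]), 2)  # median of 1, 3
})

test_that("platform merge concatenates probes over shared samples", {
  a <- randomMatrix(30, 6, seed = 1, prefix = "A")
  b <- randomMatrix(40, 6, seed = 2, prefix = "B")
  m <- suppressMessages(mergePlatforms(a, b))
  expect_equal(nrow(m), 70L)
  expect_identical(probeIds(m), c(probeIds(a), probeIds(b)))
  expect_identical(sampleIds(m), sampleIds(a))
  expect_identical(platformLabel(m), "merged")

  # identity case: no extra probes
  empty <- ExpressionMatrix(
    matrix(numeric(0), 0, 6, dimnames = list(NULL, sampleIds(a))))
  m2 <- suppressMessages(mergePlatforms(a, empty))
  expect_equal(exprValues(m2), exprValues(a))
})

test_that("merge restricts to the sample intersection in a's order", {
  va <- matrix(1:6 + 0.1, 2, 3,
               dimnames = list(c("a1_at", "a2_at"), c("s1", "s2", "s3")))
  vb <- matrix(1:6 + 0.2, 2, 3,
               dimnames = list(c("b1_at", "b2_at"), c("s2", "s3", "s4")))
  m <- suppressMessages(mergePlatforms(ExpressionMatrix(va),
                                       ExpressionMatrix(vb)))
  expect_identical(sampleIds(m), c("s2", "s3"))  # brute-force intersection

  expect_error(suppressMessages(
    mergePlatforms(ExpressionMatrix(va),
                   ExpressionMatrix(`colnames<-`(vb, c("x1", "x2", "x3"))))),
    "no sample")
  expect_error(suppressMessages(
    mergePlatforms(ExpressionMatrix(va),
                   ExpressionMatrix(`rownames<-`(vb, c("a1_at", "b2_at"))))),
    "a1_at")
})

test_that("ER filter keeps positives and conserves sample counts", {
  n <- 245
  m <- randomMatrix(3, n, seed = 5)
  meta <- data.frame(
    sample_id = sampleIds(m),
    er_status = c(rep("positive", 211), rep("negative", 34)))
  f <- suppressMessages(filterERPositive(m, meta))
  expect_equal(ncol(f), 211L)
  expect_equal(ncol(f) + sum(meta$er_status != "positive"), n)

  # all-positive identity
  meta$er_status <- "positive"
  expect_equal(exprValues(suppressMessages(filterERPositive(m, meta))),
               exprValues(m))

  # sample missing from metadata is treated as unknown and excluded
  expect_warning(
    f2 <- suppressMessages(filterERPositive(m, meta[-1, ])),
    "absent from metadata")
  expect_equal(ncol(f2), n - 1L)

  meta$er_status <- "negative"
  expect_error(suppressWarnings(suppressMessages(filterERPositive(m, meta))),
               "no ER\\+")
})

test_that("cohort summary reproduces printed-table percentages", {
  sizes <- c("T1ab" = 22, "T1c" = 104, "T2" = 117, "T3" = 6)
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(sum(sizes))),
    tumor_size = rep(names(sizes), sizes))
  cs <- summarizeCohort(meta)$categorical
  expect_equal(cs$percentage[match(names(sizes), cs$level)],
               c(8.8, 41.8, 47.0, 2.4))

  one <- summarizeCohort(data.frame(sample_id = letters[1:5], g = "x"))
  expect_equal(one$categorical$percentage, 100.0)

  two <- summarizeCohort(data.frame(sample_id = letters[1:4],
                                    g = c("a", "b", "b", "b")))
  expect_equal(two$categorical$percentage, c(25.0, 75.0))
})

test_that("cohort percentages sum to 100 and numerics are summarised", {
  for (seed in 1:5) {
    set.seed(seed)
    meta <- data.frame(
      sample_id = sprintf("S%03d", 1:97),
      grade = sample(c("1", "2", "3"), 97, replace = TRUE),
      age = round(runif(97, 28, 93)))
    cs <- summarizeCohort(meta)
    expect_lt(abs(sum(cs$categorical$percentage) - 100), 0.2)
    expect_equal(cs$numeric$median, median(meta$age))
    expect_equal(cs$numeric$min, min(meta$age))
  }
})

test_that("probe-to-symbol mapping handles shared genes and passthrough", {
  ann <- data.frame(
    probe_id = c("206170_at", "209392_at", "210839_s_at"),
    gene_symbol = c("ADRB2", "ENPP2", "ENPP2"))
  res <- mapProbesToSymbols(c("206170_at", "209392_at", "210839_s_at",
                              "ZZZ_at"), ann)
  expect_equal(unname(res), c("ADRB2", "ENPP2", "ENPP2", "ZZZ_at"),
               ignore_attr = TRUE)
  expect_equal(attr(res, "unannotated"), c(FALSE, FALSE, FALSE, TRUE))

  # platform suffix tags are stripped before lookup
  expect_equal(unname(mapProbesToSymbols("206170_at_A", ann)), "ADRB2",
               ignore_attr = TRUE)
})
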