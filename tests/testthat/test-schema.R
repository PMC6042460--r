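test_that("bundled CIHD schema has the 46-category composition", {
  sch <- load_schema("cihd")
  expect_s3_class(sch, "icf_schema")
  expect_equal(nrow(sch), 46L)
  counts <- table(sch$component)
  expect_equal(counts[["body_structure"]], 2L)
  expect_equal(counts[["body_function"]], 12L)
  expect_equal(counts[["activity_participation"]], 15L)
  expect_equal(counts[["environment"]], 17L)
  expect_false(anyDuplicated(sch$code) > 0)
  expect_equal(sch$description[sch$code == "b410"], "Heart functions")
})

test_that("schema files load with or without header and are validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("b130,body_function,Energy and drive functions,mental functions", f)
  sch <- load_schema(f)
  expect_equal(nrow(sch), 1L)
  expect_equal(sch$code, "b130")

  writeLines(c("code,component,description,chapter",
               "x130,body_function,Bad,ch"), f)
  expect_error(load_schema(f), "malformed ICF code at row 1")

  writeLines(c("code,component,description,chapter",
               "b130,body_function,A,ch",
               "b130,body_function,B,ch"), f)
  expect_error(load_schema(f), "duplicate ICF code")

  writeLines(c("code,component,description,chapter",
               "b130,environment,A,ch"), f)
  expect_error(load_schema(f), "does not match its code letter")
})

test_that("qualifier matrices round-trip through CSV and are validated", {
  sch <- tiny_schema(c("b130", "d450", "e575"))
  m <- qualifier_matrix(matrix(c(0L, 1L, 2L, 3L, 4L, 8L), 2, 3,
                               dimnames = list(c("P1", "P2"), sch$code)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_qualifier_matrix(m, f)
  m2 <- read_qualifier_matrix(f, sch)
  expect_identical(unclass(m2), unclass(m))

  # out-of-range value names the offending patient and code
  txt <- readLines(f)
  txt[2] <- sub("^P1,0", "P1,5", txt[2])
  writeLines(txt, f)
  err <- expect_error(read_qualifier_matrix(f, sch), "invalid qualifier value 5")
  expect_match(conditionMessage(err), "P1")
  expect_match(conditionMessage(err), "b130")

  # unknown code is named
  writeLines(c("patient_id,b130,q999", "P1,0,1"), f)
  expect_error(read_qualifier_matrix(f, tiny_schema("b130")), "q999|malformed")
})

test_that("missing mask marks exactly the 8/9 cells", {
  m <- qualifier_matrix(matrix(0L, 3, 2,
                               dimnames = list(NULL, c("b130", "b134"))))
  expect_false(any(missing_mask(m)))
  m[2, 2] <- 9L
  expect_equal(sum(missing_mask(m)), 1L)
  expect_true(missing_mask(m)[2, 2])

  # brute-force count on random small matrices
  set.seed(42)
  for (i in 1:20) {
    v <- matrix(sample(c(0:4, 8L, 9L), 30, replace = TRUE), 5,
                dimnames = list(NULL, sprintf("d%03d", 101:106)))
    expect_equal(sum(missing_mask(qualifier_matrix(v))),
                 sum(v == 8L) + sum(v == 9L))
  }
})
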