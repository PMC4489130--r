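test_that("simple dialect tables are read row-for-row", {
  tbl <- read_clonotype_table(extdata("repertoire_1.tsv"), dialect = "simple")
  expect_equal(nrow(tbl), 6)
  expect_equal(tbl$count, c(33L, 29L, 28L, 5L, 4L, 1L))
  expect_equal(tbl$sample_id, rep("repertoire_1", 6))
  expect_true(all(tbl$productive))
})

test_that("AIRR dialect maps junction_aa, duplicate_count and productive", {
  tbl <- read_clonotype_table(extdata("airr_example.tsv"))
  expect_setequal(
    tbl$clone_id,
    c("CARWDYW", "CAKLGGYFDYW", "CAR", "CARDYFDLW", "CTTVPQGW", "CARSSGYW"))
  expect_equal(tbl$count[tbl$clone_id == "CAKLGGYFDYW"], 6L)
  expect_false(tbl$productive[tbl$clone_id == "CTTVPQGW"])
  # two rows for the same CDR3 stay separate until aggregation
  expect_equal(sum(tbl$clone_id == "CARWDYW"), 2)
})

test_that("degenerate rows are dropped with a warning, bad files error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clone_id\tcount", "CARW\t5", "CARY\t", "\t3"), path)
  expect_warning(tbl <- read_clonotype_table(path, dialect = "simple"),
                 "dropped")
  expect_equal(nrow(tbl), 1)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("clone_id\tcount", empty)
  expect_error(read_clonotype_table(empty, dialect = "simple"), "Empty")

  badcol <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tn", "A\t1"), badcol)
  expect_error(read_clonotype_table(badcol, dialect = "simple"), "clone_id")
})

test_that("preprocessing filters enforce productivity, length and abundance", {
  rec <- tibble::tibble(
    sample_id = "s",
    clone_id = c("CARW", "CAR", "CARDY", "CTTVPQGW"),
    count = c(2L, 10L, 1L, 5L),
    productive = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- filter_clonotypes(rec)
  expect_equal(out$clone_id, "CARW")   # length-3 CDR3, singleton and
  expect_equal(out$count, 2L)          # non-productive clones all removed
})

test_that("counts aggregate over exact clone identity before the abundance filter", {
  rec <- tibble::tibble(
    sample_id = "s",
    clone_id = c("CARW", "CARW", "CASSL"),
    count = c(1L, 1L, 1L),
    productive = TRUE
  )
  out <- filter_clonotypes(rec)
  # two singleton reads of the same CDR3 form one clone of abundance 2
  expect_equal(out$clone_id, "CARW")
  expect_equal(out$count, 2L)
})

test_that("filtering is idempotent and can empty a repertoire with an error", {
  rec <- read_clonotype_table(extdata("airr_example.tsv"))
  once <- filter_clonotypes(rec)
  twice <- filter_clonotypes(once)
  expect_equal(once, twice)
  expect_error(filter_clonotypes(once, min_abundance = 1e6), "removed")
})

test_that("clonal frequencies normalize, sort and aggregate", {
  expect_equal(
    clonal_frequencies(tibble::tibble(clone_id = c("A", "B"),
                                      count = c(2L, 2L)))$frequency,
    c(0.5, 0.5))
  f1 <- clonal_frequencies(read_clonotype_table(extdata("repertoire_1.tsv")))
  expect_equal(f1$frequency, example_f1)
  single <- clonal_frequencies(tibble::tibble(clone_id = "A", count = 7L))
  expect_equal(single$frequency, 1)
})

test_that("frequencies sum to one and ignore input order", {
  withr::local_seed(41)
  for (rep in 1:25) {
    n <- sample(2:200, 1)
    rec <- tibble::tibble(
      clone_id = paste0("c", seq_len(n)),
      count = sample(1:1000, n, replace = TRUE)
    )
    out <- clonal_frequencies(rec)
    expect_equal(sum(out$frequency), 1, tolerance = 1e-9)
    shuffled <- clonal_frequencies(rec[sample(n), ])
    expect_equal(
      shuffled[order(shuffled$clone_id), c("clone_id", "frequency")],
      out[order(out$clone_id), c("clone_id", "frequency")])
  }
})

test_that("profile tables round-trip through CSV", {
  prof <- repertoire_profiles(
    clonal_frequencies(read_clonotype_table(extdata("repertoire_1.tsv"))),
    alpha_grid(0, 4, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(prof, path)
  back <- read_profiles(path)
  expect_equal(back$diversity, prof$diversity)
  expect_equal(back$alpha, prof$alpha)
})

test_that("metadata tables require sample_id and status_label", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstatus_label", "s1\tBaseline", "s2\tMonth 2"), path)
  meta <- read_sample_metadata(path)
  expect_equal(meta$status_label, c("Baseline", "Month 2"))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup", "s1\ta"), bad)
  expect_error(read_sample_metadata(bad), "status_label")
})
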