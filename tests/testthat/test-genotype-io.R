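# genotype matrix container, table IO, and missingness filters

test_that("construction validates ids, call range and ploidy coverage", {
  calls <- tiny_calls(rbind(c(0, 2, 4, 1), c(1, NA, 3, 0), c(4, 4, 0, 2)))
  m <- genotype_matrix(calls, ploidy = c(a1 = 4L, a2 = 4L, a3 = 2L))
  expect_s3_class(m, "genotype_matrix")
  expect_equal(n_accessions(m), 3L)
  expect_equal(n_markers(m), 4L)

  bad <- calls
  bad[1, 1] <- 5L
  expect_error(genotype_matrix(bad), "outside 0\\.\\.4")
  expect_error(genotype_matrix(calls, encoding = "three_cluster"),
               "outside 0\\.\\.2")
  dup <- calls
  rownames(dup) <- c("a1", "a1", "a3")
  expect_error(genotype_matrix(dup), "duplicate accession ids")
  expect_error(genotype_matrix(calls, ploidy = c(a1 = 4L)), "no ploidy")
})

test_that("read/write round trip is lossless on random matrices", {
  for (seed in 1:50) {
    m <- random_genotype_matrix(n = sample(1:8, 1), m = sample(1:10, 1),
                                missing = 0.2, seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_genotype_table(m, path)
    back <- read_genotype_table(path)
    expect_identical(back$calls, m$calls)
  }
  # and a second serialisation of the re-read matrix is byte-identical
  m <- random_genotype_matrix(6, 9, seed = 99)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(m, p1)
  write_genotype_table(read_genotype_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("degenerate tables are written and read faithfully", {
  empty <- genotype_matrix(matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("m1", "m2", "m3"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(empty, path)
  expect_length(readLines(path), 1L)  # header only

  one <- genotype_matrix(tiny_calls(matrix(NA_integer_, 1, 1)))
  write_genotype_table(one, path)
  expect_equal(strsplit(readLines(path)[2], "\t")[[1]][2], "NA")
  expect_true(is.na(read_genotype_table(path)$calls[1, 1]))
})

test_that("malformed cells are reported with row and column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession_id\tm1\tm2", "a1\t2\tx", "a2\t0\t1"), path)
  expect_error(read_genotype_table(path), "malformed cell 'x'.*a1.*m2")
  writeLines(c("accession_id\tm1", "a1\t7"), path)
  expect_error(read_genotype_table(path), "outside 0\\.\\.4")
})

test_that("sample filter removes at the threshold and matches a recount", {
  set.seed(42)
  n <- 100L; mk <- 40L
  calls <- matrix(sample(0:4, n * mk, TRUE), n, mk,
                  dimnames = list(sprintf("s%03d", 1:n),
                                  sprintf("m%02d", 1:mk)))
  n_miss <- sample(0:mk, n, TRUE)
  for (i in 1:n) if (n_miss[i] > 0) calls[i, sample(mk, n_miss[i])] <- NA
  m <- genotype_matrix(calls)
  out <- filter_samples(m, 0.20)
  oracle_removed <- rownames(calls)[rowSums(is.na(calls)) / mk >= 0.20]
  expect_setequal(out$report$removed$accession_id, oracle_removed)
  expect_equal(nrow(out$matrix$calls) + nrow(out$report$removed), n)
  expect_true(all(out$report$removed$missing_fraction >= 0.20))

  # exactly 20% missing is removed ("20% or more"); 0% retained
  b <- tiny_calls(rbind(c(NA, 0, 1, 2, 3), c(0, 1, 2, 3, 4)))
  fb <- filter_samples(genotype_matrix(b), 0.20)
  expect_equal(fb$report$removed$accession_id, "a1")
  expect_equal(rownames(fb$matrix$calls), "a2")
})

test_that("marker filter removes at the threshold and matches a recount", {
  set.seed(7)
  n <- 30L; mk <- 120L
  calls <- matrix(sample(0:4, n * mk, TRUE), n, mk,
                  dimnames = list(sprintf("s%02d", 1:n),
                                  sprintf("m%03d", 1:mk)))
  calls[runif(n * mk) < 0.08] <- NA
  m <- genotype_matrix(calls)
  out <- filter_markers(m, 0.10)
  oracle_removed <- colnames(calls)[colSums(is.na(calls)) / n >= 0.10]
  expect_setequal(out$report$removed$marker_id, oracle_removed)
  expect_equal(ncol(out$matrix$calls) + nrow(out$report$removed), mk)

  # marker missing in exactly 10% of individuals goes; fully called stays
  b <- matrix(0L, 10, 2, dimnames = list(paste0("s", 1:10), c("mA", "mB")))
  b[1, 1] <- NA
  fb <- filter_markers(genotype_matrix(b), 0.10)
  expect_equal(fb$report$removed$marker_id, "mA")
  expect_equal(colnames(fb$matrix$calls), "mB")
})

test_that("each filter is idempotent", {
  m <- random_genotype_matrix(50, 60, missing = 0.15, seed = 3)
  s1 <- filter_samples(m, 0.2)$matrix
  s2 <- filter_samples(s1, 0.2)$matrix
  expect_identical(s1$calls, s2$calls)
  k1 <- filter_markers(s1, 0.1)$matrix
  k2 <- filter_markers(k1, 0.1)$matrix
  expect_identical(k1$calls, k2$calls)
})

test_that("curated marker exclusion accepts vectors and files", {
  m <- random_genotype_matrix(4, 6, seed = 5)
  drop <- colnames(m$calls)[c(2, 4)]
  expect_equal(colnames(exclude_markers(m, drop)$calls),
               setdiff(colnames(m$calls), drop))
  f <- withr::local_tempfile()
  writeLines(drop, f)
  expect_equal(colnames(exclude_markers(m, f)$calls),
               setdiff(colnames(m$calls), drop))
})

test_that("metadata IO enforces the controlled vocabulary", {
  meta <- data.frame(accession_id = c("a1", "a2"),
                     species_code = c("ADG", "PHU"),
                     declared_ploidy = c(4L, NA),
                     country = c("Peru", NA),
                     sample_role = c("mother", "single"),
                     pair_id = c("a1", NA))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metadata(meta, f)
  back <- read_metadata(f)
  expect_equal(back$species_code, meta$species_code)
  meta_bad <- meta
  meta_bad$species_code[1] <- "XYZ"
  write_metadata(meta_bad, f)
  expect_error(read_metadata(f), "unknown species codes: XYZ")
})

test_that("array classes convert to dosages by the nearest-class inverse", {
  calls <- tiny_calls(rbind(c(0, 2, 4), c(0, 1, 3), c(1, 2, 3)))
  pl <- c(a1 = 2L, a2 = 3L, a3 = 4L)
  d <- as_dosage(genotype_matrix(calls, ploidy = pl))
  expect_equal(unname(d["a1", ]), c(0L, 1L, 2L))  # diploid AB class = 2
  expect_equal(unname(d["a2", ]), c(0L, 1L, 2L))  # triploid 1/3, 2/3
  expect_equal(unname(d["a3", ]), c(1L, 2L, 3L))  # tetraploid identity
})
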