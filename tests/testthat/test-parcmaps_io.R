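test_that("parcellation_meta enforces its invariants", {
  meta <- tiny_meta(5)
  expect_s3_class(meta, "parcellation_meta")
  expect_equal(sqrt(rowSums(meta$centroid^2)), rep(1, 10),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(parcellation_meta(c("a", "a"), c("L", "R"), diag(3)[1:2, ],
                                 c("x", "x"), c("y", "y")),
               "duplicate")
  expect_error(parcellation_meta(c("a", "b"), c("L", "M"), diag(3)[1:2, ],
                                 c("x", "x"), c("y", "y")),
               "hemisphere")
  bad <- diag(3)[1:2, ] * 2
  expect_error(parcellation_meta(c("a", "b"), c("L", "R"), bad,
                                 c("x", "x"), c("y", "y")),
               "unit sphere")
})

test_that("read_parcel_table reorders shuffled rows to meta order", {
  meta <- tiny_meta(34)
  v <- seq_len(68)
  f <- tempfile(fileext = ".tsv")
  shuffle <- sample(68)
  writeLines(c("region_id\tthickness",
               paste(meta$region_id[shuffle], v[shuffle], sep = "\t")), f)
  pm <- read_parcel_table(f, meta)
  expect_s3_class(pm, "parcel_map")
  expect_equal(unname(pm$values), v)
})

test_that("missing, duplicate, unknown and non-numeric rows are rejected by name", {
  meta <- tiny_meta(34)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("region_id\tv",
               paste(meta$region_id[-5], 1, sep = "\t")), f)
  expect_error(read_parcel_table(f, meta), meta$region_id[5])
  writeLines(c("region_id\tv",
               paste(c(meta$region_id, meta$region_id[2]), 1, sep = "\t")), f)
  expect_error(read_parcel_table(f, meta), "duplicate")
  writeLines(c("region_id\tv",
               paste(c(meta$region_id, "lh_not_a_region"), 1, sep = "\t")), f)
  expect_error(read_parcel_table(f, meta), "lh_not_a_region")
  vals <- as.character(seq_len(68)); vals[7] <- "oops"
  writeLines(c("region_id\tmyvalue", paste(meta$region_id, vals, sep = "\t")), f)
  expect_error(read_parcel_table(f, meta), "myvalue")
})

test_that("empty cells become an explicit mask, and comma files are sniffed", {
  meta <- tiny_meta(3)
  f <- tempfile(fileext = ".csv")
  vals <- as.character(1:6); vals[2] <- ""
  writeLines(c("region_id,v", paste(meta$region_id, vals, sep = ",")), f)
  pm <- read_parcel_table(f, meta)
  expect_true(pm$mask[2])
  expect_equal(sum(pm$mask), 1L)
})

test_that("write-then-read round-trips values and is byte-deterministic", {
  meta <- tiny_meta(10)
  set.seed(42)
  em <- effect_matrix(matrix(rnorm(20 * 6) * 10^runif(120, -6, 6), 20), meta)
  f1 <- tempfile(); f2 <- tempfile()
  write_parcel_table(em, f1)
  write_parcel_table(em, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_parcel_table(f1, meta, "effects")
  expect_equal(back$values, em$values, tolerance = 1e-12)
  # 6 conditions -> 7 columns on disk
  expect_length(strsplit(readLines(f1, n = 1L), "\t")[[1L]], 7L)

  pm <- parcel_map(rnorm(20), meta, "m")
  f3 <- tempfile()
  write_parcel_table(pm, f3)
  expect_equal(read_parcel_table(f3, meta)$values, pm$values, tolerance = 1e-12)
})

test_that("parcellation meta round-trips through its TSV form", {
  meta <- tiny_meta(7)
  f <- tempfile()
  write_parcellation_meta(meta, f)
  back <- read_parcellation_meta(f)
  expect_equal(back$region_id, meta$region_id)
  expect_equal(back$centroid, meta$centroid, tolerance = 1e-12)
  expect_equal(as.character(back$community), as.character(meta$community))
})

test_that("align_sources restricts to the common subset, order preserved", {
  meta68 <- tiny_meta(34)
  drop <- c(1, 5, 9, 35, 40, 44)            # three regions per hemisphere
  meta62 <- subset_meta(meta68, setdiff(1:68, drop))
  m1 <- parcel_map(seq_len(68), meta68, "full")
  m2 <- parcel_map(seq_len(62), meta62, "partial")
  out <- align_sources(m1, m2)
  expect_equal(attr(out, "n_common"), 62L)
  expect_equal(out[[1]]$meta$region_id, meta62$region_id)
  expect_equal(unname(out[[1]]$values), setdiff(1:68, drop))
  # idempotent and identity on already-aligned inputs
  again <- align_sources(out[[1]], out[[2]])
  expect_identical(again[[1]]$values, out[[1]]$values)
  expect_identical(align_sources(m1, m1)[[1]]$values, m1$values)
})

test_that("align_sources rejects disjoint region sets", {
  meta <- tiny_meta(4)
  a <- parcel_map(1:4, subset_meta(meta, 1:4))
  b <- parcel_map(1:4, subset_meta(meta, 5:8))
  expect_error(align_sources(a, b), "no regions")
})
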