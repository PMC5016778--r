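test_that("packaged reference table has the expected structure and cells", {
  d <- packaged_table1()
  expect_s3_class(d, "study_dataset")
  expect_equal(nrow(d), 30)
  expect_equal(sum(d$island == "Moorea"), 16)
  expect_equal(sum(d$island %in% c("VancouverEast", "VancouverWest")), 14)
  expect_equal(sum(d$island == "VancouverEast"), 8)

  ti <- d[d$site_id == "M-Ti", ]
  expect_equal(ti$status_local, 5)
  expect_equal(ti$aquaculture, 0.079365079)
  expect_equal(ti$nis_prop, 0)
  expect_equal(ti$n_native, 1)
  expect_equal(ti$simpson, 0)

  ci <- d[d$site_id == "V-CI", ]
  expect_equal(ci$aquaculture, 5)
  expect_equal(ci$nis_prop, 0.5)
})

test_that("fixture column means match the regional descriptive statistics", {
  d <- packaged_table1()
  expect_identical(mean(d$substrate[d$island == "Moorea"]), 3.625)
  expect_equal(mean(d$traffic[d$island != "Moorea"]), 40 / 14, tolerance = 1e-12)
  expect_equal(mean(d$traffic[d$island == "Moorea"]), 2.5625)
})

test_that("read/write round trip preserves every numeric cell exactly", {
  d <- packaged_table1()
  tmp <- tempfile(fileext = ".csv")
  write_dataset(d, tmp)
  d2 <- read_dataset(tmp)
  for (cn in setdiff(names(d), c("site_id", "island"))) {
    expect_identical(d2[[cn]], d[[cn]], label = cn)
  }
  expect_identical(d2$site_id, d$site_id)
})

test_that("reader reports schema and validation problems by name", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("", tmp)
  expect_error(read_dataset(tmp))

  d <- random_study_df(6)
  write.csv(d[, -3], tmp, row.names = FALSE)  # drop status_local
  expect_error(read_dataset(tmp), "status_local")

  d_dup <- d
  d_dup$site_id[2] <- d_dup$site_id[1]
  write.csv(d_dup, tmp, row.names = FALSE)
  expect_error(read_dataset(tmp), "duplicated site_id")

  d_bad <- d
  d_bad$aquaculture <- as.character(d_bad$aquaculture)
  d_bad$aquaculture[3] <- "high"
  write.csv(d_bad, tmp, row.names = FALSE)
  expect_error(read_dataset(tmp), "aquaculture")

  d_na <- d
  d_na$traffic[4] <- NA
  write.csv(d_na, tmp, row.names = FALSE)
  expect_error(read_dataset(tmp), "missing")
})

test_that("dialect mapping renames file columns onto the canonical schema", {
  d <- random_study_df(6)
  names(d)[names(d) == "nis_prop"] <- "NIS"
  tmp <- tempfile(fileext = ".csv")
  write.csv(d, tmp, row.names = FALSE)
  expect_error(read_dataset(tmp), "nis_prop")
  d2 <- read_dataset(tmp, dialect = c(nis_prop = "NIS"))
  expect_equal(d2$nis_prop, d$NIS)
  expect_error(read_dataset(tmp, dialect = c(nis_prop = "absent")), "absent")
})

test_that("regional subsets have the regional sample sizes and keep order", {
  d <- packaged_table1()
  expect_equal(nrow(subset(d, islands = "Moorea")), 16)
  expect_equal(nrow(subset(d, islands = c("VancouverEast", "Moorea"))), 24)
  expect_equal(nrow(subset(d, islands = c("VancouverWest", "Moorea"))), 22)
  expect_equal(nrow(subset(d, islands = c("VancouverEast", "VancouverWest"))), 14)
  full <- subset(d, islands = c("Moorea", "VancouverEast", "VancouverWest"))
  expect_identical(full$site_id, d$site_id)
  expect_error(subset(d, islands = "Atlantis"), "empty subset")
})

test_that("validation enforces the domain invariants", {
  d <- random_study_df(6)
  d_bad <- d; d_bad$status_local[1] <- 4
  expect_error(study_dataset(d_bad), "status_local")
  d_bad <- d; d_bad$nis_prop[1] <- 1.2
  expect_error(study_dataset(d_bad), "nis_prop")
  d_bad <- d; d_bad$simpson[1] <- 1
  expect_error(study_dataset(d_bad), "simpson")
})
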