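test_that("wavelength grid spans 1100-2498 nm at 2 nm over 700 channels", {
  g <- wavelength_grid()
  wl <- wavelengths(g)
  expect_length(wl, 700)
  expect_equal(wl[1], 1100)
  expect_equal(wl[700], 2498)
  expect_true(all(diff(wl) == 2))
})

test_that("dataset constructor validates shapes and missing values", {
  g <- tiny_grid()
  X <- matrix(rnorm(5 * 96), 5)
  Y <- matrix(runif(20, 1, 10), 5)
  ds <- spectra_dataset(X, Y, g)
  expect_s3_class(ds, "spectra_dataset")
  expect_equal(dim(ds), c(5L, 96L))
  expect_error(spectra_dataset(X, Y[1:4, ], g), "row-count mismatch")
  expect_error(spectra_dataset(X[, 1:90], Y, g), "channels")
  X[2, 3] <- NA
  expect_error(spectra_dataset(X, Y, g), "missing")
})

test_that("write/read round-trips a dataset within 1e-9", {
  ds <- tiny_dataset(n = 3L)
  dir <- withr::local_tempdir()
  paths <- write_spectra_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read_spectra_dataset(paths["spectra"], paths["labels"])
  expect_equal(back$X, ds$X, tolerance = 1e-9)
  expect_equal(back$Y, ds$Y, tolerance = 1e-9)
  expect_equal(back$grid, ds$grid)
})

test_that("packed-array dialect round-trips exactly", {
  ds <- tiny_dataset(n = 4L)
  dir <- withr::local_tempdir()
  paths <- write_spectra_dataset(ds, dir, dialect = "packed-array")
  back <- read_spectra_dataset(paths["spectra"], paths["labels"],
                               dialect = "packed-array")
  expect_identical(back$X, ds$X)
  expect_identical(back$Y, ds$Y)
})

test_that("empty dataset writes header-only files that re-read as N = 0", {
  g <- tiny_grid()
  ds <- spectra_dataset(matrix(numeric(0), 0, 96), matrix(numeric(0), 0, 4), g)
  dir <- withr::local_tempdir()
  paths <- write_spectra_dataset(ds, dir)
  expect_equal(length(readLines(paths["spectra"])), 1L) # header only
  back <- read_spectra_dataset(paths["spectra"], paths["labels"])
  expect_equal(nrow(back$X), 0L)
})

test_that("a full-size dataset writes one data row per sample", {
  ds <- generate_spectra(generator_config(seed = 9L))
  dir <- withr::local_tempdir()
  paths <- write_spectra_dataset(ds, dir)
  expect_equal(length(readLines(paths["spectra"])) - 1L, 80L)
})

test_that("reader reports row mismatches and bad cells with location", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "s.csv"); lb <- file.path(dir, "l.csv")
  writeLines(c("1,2,3", "4,5,6"), sp)
  writeLines("7,8,9,10", lb)
  g3 <- wavelength_grid(n_channels = 3)
  expect_error(read_spectra_dataset(sp, lb, grid = g3), "2 rows.*1")
  writeLines(c("1,2,3", "4,x,6"), sp)
  writeLines(c("7,8,9,10", "1,2,3,4"), lb)
  expect_error(read_spectra_dataset(sp, lb, grid = g3), "row 2, column 2")
  writeLines(c("1,2", "4,5"), sp)
  expect_error(read_spectra_dataset(sp, lb, grid = g3), "2 fields, expected 3")
  expect_error(read_spectra_dataset(file.path(dir, "none.csv"), lb),
               "not found")
})

test_that("labels with a named header are reordered to canonical order", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "s.csv"); lb <- file.path(dir, "l.csv")
  writeLines("0.1,0.2,0.3", sp)
  writeLines(c("# protein,oil,starch,moisture", "64,8,3,10"), lb)
  ds <- read_spectra_dataset(sp, lb, grid = wavelength_grid(n_channels = 3))
  expect_equal(unname(ds$Y[1, ]), c(10, 3, 8, 64))
})

test_that("splitting is a seeded, exhaustive, disjoint partition", {
  ds <- generate_spectra(generator_config(seed = 4L))
  parts <- split_spectra(ds, c(0.6, 0.2, 0.2), seed = 7L)
  expect_equal(sapply(parts, function(p) nrow(p$X)),
               c(train = 48L, val = 16L, test = 16L))
  ids <- c(parts$train$sample_ids, parts$val$sample_ids, parts$test$sample_ids)
  expect_setequal(ids, ds$sample_ids)
  expect_equal(length(ids), length(unique(ids)))
  again <- split_spectra(ds, c(0.6, 0.2, 0.2), seed = 7L)
  expect_identical(again$train$sample_ids, parts$train$sample_ids)
  expect_error(split_spectra(ds, c(0.5, 0.2, 0.2), seed = 1), "sum to 1")
  two <- spectra_dataset(ds$X[1:2, ], ds$Y[1:2, ], ds$grid)
  expect_error(split_spectra(two, seed = 1), "at least 3")
})

test_that("constituent stats match hand arithmetic and bracket the data", {
  g <- tiny_grid()
  Y <- cbind(rep(5, 2), c(1, 3), c(2, 4), c(7, 9))
  ds <- spectra_dataset(matrix(0.1, 2, 96), Y, g)
  st <- constituent_stats(ds)
  expect_equal(st$mean, c(5, 2, 3, 8))
  expect_equal(st$std[1], 0)
  expect_equal(st$std[2], 1) # population divisor
  st_s <- constituent_stats(ds, divisor = "sample")
  expect_equal(st_s$std[2], sqrt(2))
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
  expect_equal(st$count, rep(2L, 4))
})

test_that("large-sample stats agree with generator parameters", {
  cfg <- generator_config(n_samples = 2000L, seed = 31L)
  ds <- generate_spectra(cfg)
  st <- constituent_stats(ds)
  se <- cfg$constituent_stds / sqrt(2000)
  expect_true(all(abs(st$mean - cfg$constituent_means) < 3 * se))
  expect_true(all(st$min <= st$mean & st$mean <= st$max))
})
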