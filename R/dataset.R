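#' Wavelength grid for a spectra dataset
#'
#' A grid is stored compactly as (start, step, n): channel `i` (0-based)
#' sits at `start_nm + i * step_nm`. The corn benchmark grid is 1100 nm to
#' 2498 nm at 2 nm spacing, i.e. 700 channels.
#'
#' @param start_nm First channel wavelength in nm.
#' @param step_nm Channel spacing in nm (must be positive).
#' @param n_channels Number of channels.
#' @return A `wavelength_grid` object.
#' @examples
#' g <- wavelength_grid()
#' range(wavelengths(g)) # 1100 2498
#' @export
wavelength_grid <- function(start_nm = 1100, step_nm = 2, n_channels = 700L) {
  stopifnot(step_nm > 0, n_channels >= 1)
  structure(list(start_nm = start_nm, step_nm = step_nm,
                 n_channels = as.integer(n_channels)),
            class = "wavelength_grid")
}

#' @rdname wavelength_grid
#' @param grid A `wavelength_grid`.
#' @export
wavelengths <- function(grid) {
  grid$start_nm + grid$step_nm * (seq_len(grid$n_channels) - 1)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm, %d channels\n",
              x$start_nm, x$start_nm + x$step_nm * (x$n_channels - 1),
              x$step_nm, x$n_channels))
  invisible(x)
}

#' The fixed constituent order
#'
#' All concentration tables use the column order moisture, starch, oil,
#' protein; readers reorder by header name when one is present.
#' @export
constituent_names <- function() c("moisture", "starch", "oil", "protein")

#' Construct a spectra dataset
#'
#' Pairs an `N x n_channels` absorbance matrix with an `N x 4` table of
#' constituent concentrations (percent) on a shared wavelength grid.
#'
#' @param X Numeric matrix of absorbance values, one spectrum per row.
#' @param Y Numeric matrix with 4 columns in the order of
#'   [constituent_names()].
#' @param grid A [wavelength_grid()].
#' @param sample_ids Character vector of row identifiers.
#' @return A `spectra_dataset` object.
#' @export
spectra_dataset <- function(X, Y, grid = wavelength_grid(),
                            sample_ids = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    stop("row-count mismatch: ", nrow(X), " spectra vs ", nrow(Y), " label rows",
         call. = FALSE)
  }
  if (nrow(X) > 0 && ncol(X) != grid$n_channels) {
    stop("spectra have ", ncol(X), " channels but the grid declares ",
         grid$n_channels, call. = FALSE)
  }
  if (nrow(Y) > 0 && ncol(Y) != 4L) {
    stop("labels must have 4 columns (", paste(constituent_names(),
         collapse = ", "), ")", call. = FALSE)
  }
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(X)))
  stopifnot(length(sample_ids) == nrow(X))
  colnames(Y) <- constituent_names()
  structure(list(X = unname(X), Y = Y, grid = grid,
                 constituents = constituent_names(),
                 sample_ids = as.character(sample_ids)),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d samples x %d channels (%g-%g nm)\n",
              nrow(x$X), x$grid$n_channels, x$grid$start_nm,
              x$grid$start_nm + x$grid$step_nm * (x$grid$n_channels - 1)))
  if (nrow(x$X) > 0) {
    cat("constituent means (%):",
        paste(sprintf("%s %.2f", x$constituents, colMeans(x$Y)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$X)

# Row subset helper used by splitting and augmentation.
ds_subset <- function(ds, idx) {
  spectra_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx, , drop = FALSE],
                  ds$grid, ds$sample_ids[idx])
}

#' @export
as_tibble.spectra_dataset <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$Y)) |>
    dplyr::mutate(sample_id = x$sample_ids, .before = 1L)
}

#' Read a spectra dataset from disk
#'
#' Reads paired spectra and label files. The delimited-text dialect is
#' comma-separated with `.` decimals and an optional `#`-prefixed header
#' row; a spectra header holds wavelengths, a label header constituent
#' names (labels are reordered to the canonical order when named). The
#' packed-array dialect is a serialized R matrix pair as written by
#' [write_spectra_dataset()].
#'
#' @param spectra_path,labels_path File paths.
#' @param dialect `"delimited-text"` or `"packed-array"`.
#' @param grid Grid to use when the spectra file has no wavelength header.
#' @return A [spectra_dataset()].
#' @export
read_spectra_dataset <- function(spectra_path, labels_path,
                                 dialect = c("delimited-text", "packed-array"),
                                 grid = NULL) {
  dialect <- match.arg(dialect)
  for (p in c(spectra_path, labels_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (dialect == "packed-array") {
    X <- readRDS(spectra_path)
    lab <- readRDS(labels_path)
    Y <- lab$Y
    if (is.null(grid)) grid <- lab$grid
    ids <- lab$sample_ids
  } else {
    sp <- read_delim_matrix(spectra_path)
    lb <- read_delim_matrix(labels_path)
    X <- sp$m; Y <- lb$m
    if (!is.null(lb$header)) {
      ord <- match(constituent_names(), tolower(lb$header))
      if (!anyNA(ord)) Y <- Y[, ord, drop = FALSE]
    }
    if (is.null(grid)) {
      grid <- if (!is.null(sp$header)) {
        wl <- suppressWarnings(as.numeric(sp$header))
        if (anyNA(wl)) wavelength_grid(n_channels = ncol(X))
        else wavelength_grid(wl[1L], if (length(wl) > 1) wl[2L] - wl[1L] else 2,
                             length(wl))
      } else {
        wavelength_grid(n_channels = max(ncol(X), 1L))
      }
    }
    ids <- NULL
  }
  if (nrow(X) != nrow(Y)) {
    stop("row-count mismatch: spectra file has ", nrow(X),
         " rows, labels file has ", nrow(Y), call. = FALSE)
  }
  if (nrow(X) > 0 && ncol(X) != grid$n_channels) {
    stop("spectra rows have ", ncol(X), " fields, expected ",
         grid$n_channels, call. = FALSE)
  }
  spectra_dataset(X, Y, grid, ids)
}

# Comma-delimited numeric matrix with optional '#'-prefixed header.
read_delim_matrix <- function(path) {
  lines <- readLines(path)
  header <- NULL
  if (length(lines) > 0 && startsWith(lines[1L], "#")) {
    header <- trimws(strsplit(sub("^#\\s*", "", lines[1L]), ",")[[1L]])
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    nc <- if (is.null(header)) 0L else length(header)
    return(list(m = matrix(numeric(0), 0L, nc), header = header))
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  nc <- length(cells[[1L]])
  m <- matrix(NA_real_, length(cells), nc)
  for (i in seq_along(cells)) {
    row <- suppressWarnings(as.numeric(cells[[i]]))
    if (length(row) != nc) {
      stop("row ", i, " of ", path, " has ", length(row),
           " fields, expected ", nc, call. = FALSE)
    }
    if (anyNA(row)) {
      stop("non-numeric value at row ", i, ", column ",
           which(is.na(row))[1L], " of ", path, call. = FALSE)
    }
    m[i, ] <- row
  }
  list(m = m, header = header)
}

#' Write a spectra dataset to disk
#'
#' Writes `spectra.csv` (wavelength header + one spectrum per row) and
#' `labels.csv` (constituent header) at 12 significant digits so that
#' [read_spectra_dataset()] round-trips within 1e-9.
#'
#' @param ds A [spectra_dataset()].
#' @param out_dir Output directory (created if missing).
#' @param dialect `"delimited-text"` (CSV) or `"packed-array"` (serialized
#'   matrices, exact round-trip).
#' @return Named character vector with the two file paths.
#' @export
write_spectra_dataset <- function(ds, out_dir,
                                  dialect = c("delimited-text", "packed-array")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir, call. = FALSE)
  if (dialect == "packed-array") {
    spectra_path <- file.path(out_dir, "spectra.rds")
    labels_path <- file.path(out_dir, "labels.rds")
    saveRDS(ds$X, spectra_path)
    saveRDS(list(Y = ds$Y, grid = ds$grid, sample_ids = ds$sample_ids),
            labels_path)
    return(c(spectra = spectra_path, labels = labels_path))
  }
  spectra_path <- file.path(out_dir, "spectra.csv")
  labels_path <- file.path(out_dir, "labels.csv")
  fmt <- function(m) apply(m, 1L, function(r) {
    paste(formatC(r, format = "g", digits = 12), collapse = ",")
  })
  wl_header <- paste0("# ", paste(formatC(wavelengths(ds$grid), format = "g",
                                          digits = 12), collapse = ","))
  writeLines(c(wl_header, if (nrow(ds$X) > 0) fmt(ds$X)), spectra_path)
  lb_header <- paste0("# ", paste(ds$constituents, collapse = ","))
  writeLines(c(lb_header, if (nrow(ds$Y) > 0) fmt(ds$Y)), labels_path)
  c(spectra = spectra_path, labels = labels_path)
}

#' Split a dataset into train/validation/test parts
#'
#' Deterministic seeded partition. Sizes are `round(fractions * N)` with the
#' last part absorbing the rounding remainder so the three parts always sum
#' to `N`.
#'
#' @param ds A [spectra_dataset()].
#' @param fractions Three positive numbers summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @return Named list with elements `train`, `val`, `test`.
#' @export
split_spectra <- function(ds, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  n <- nrow(ds$X)
  if (n < 3L) stop("need at least 3 samples to form three non-empty parts",
                   call. = FALSE)
  sizes <- round(fractions * n)
  sizes[3L] <- n - sizes[1L] - sizes[2L]
  perm <- withr::with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  list(train = ds_subset(ds, perm[seq_len(sizes[1L])]),
       val = ds_subset(ds, perm[(ends[1L] + 1L):ends[2L]]),
       test = ds_subset(ds, perm[(ends[2L] + 1L):ends[3L]]))
}

#' Per-constituent descriptive statistics
#'
#' Count, min, max, mean and standard deviation per constituent, the layout
#' of the benchmark's descriptive table. The default standard deviation
#' uses the population divisor `N`; set `divisor = "sample"` for `N - 1`.
#'
#' @param ds A [spectra_dataset()].
#' @param divisor `"population"` (divide by N) or `"sample"` (N - 1).
#' @return A tibble with one row per constituent.
#' @export
constituent_stats <- function(ds, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  stopifnot(nrow(ds$Y) >= 1)
  n <- nrow(ds$Y)
  sdv <- apply(ds$Y, 2L, function(v) {
    s2 <- sum((v - mean(v))^2)
    sqrt(s2 / if (divisor == "population") n else max(n - 1L, 1L))
  })
  tibble::tibble(
    constituent = ds$constituents,
    count = n,
    min = unname(apply(ds$Y, 2L, min)),
    max = unname(apply(ds$Y, 2L, max)),
    mean = unname(colMeans(ds$Y)),
    std = unname(sdv)
  )
}
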