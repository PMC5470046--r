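#' Read and write TIFF images
#'
#' `write_image()` stores a single plane or a list of planes (one TIFF page
#' per frame/channel, order preserved). Integer modes (`bits = 8` or `16`)
#' require values inside `[0, 2^bits - 1]` — out-of-range values raise a
#' saturation error rather than clipping silently — and round to integers.
#' Float mode (`bits = 32`) stores IEEE float32 and requires values in
#' `[0, 1]` (the range the TIFF reader maps floats onto); arbitrary-scale
#' intensities should be stored as 16-bit integers.
#'
#' `read_image()` returns an [image_plane()] (or list of planes for a
#' multi-page file); integer files are read back on their original integer
#' scale.
#'
#' @param img Numeric matrix, [image_plane()], or list of them.
#' @param path File path.
#' @param bits Bits per sample: 8, 16 (integer) or 32 (float).
#' @return `write_image()`: `path`, invisibly. `read_image()`: an
#'   [image_plane()] or list of them.
#' @export
write_image <- function(img, path, bits = 16L) {
  frames <- if (is.list(img)) img else list(img)
  if (!bits %in% c(8L, 16L, 32L)) {
    abort("unsupported bit depth: use 8, 16 (integer) or 32 (float).")
  }
  prep <- lapply(frames, function(fr) {
    m <- as_matrix(fr)
    if (any(!is.finite(m))) abort("cannot write non-finite pixel values.")
    if (bits == 32L) {
      if (min(m) < 0 || max(m) > 1) {
        abort("float TIFF requires values in [0, 1]; rescale or use 16-bit.")
      }
      return(m)
    }
    top <- 2^bits - 1
    if (min(m) < 0 || max(m) > top) {
      abort(sprintf(
        "%d-bit saturation: values span [%.4g, %.4g], outside [0, %d].",
        bits, min(m), max(m), as.integer(top)
      ))
    }
    round(m) / top
  })
  tiff::writeTIFF(if (length(prep) == 1L) prep[[1]] else prep, path,
                  bits.per.sample = as.integer(bits))
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size_um,channel Metadata attached to the returned plane(s).
#' @export
read_image <- function(path, pixel_size_um = 0.135, channel = "marker") {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  planes <- lapply(pages, function(p) {
    info <- attributes(p)
    m <- matrix(as.numeric(p), nrow(p), ncol(p))
    bps <- info$bits.per.sample %||% 16L
    if (!bps %in% c(8L, 16L, 32L)) {
      abort(sprintf("unsupported TIFF bit depth: %d.", bps))
    }
    if (bps == 32L) {
      # float page: as.is reinterprets; reread normally
      m <- NULL
    }
    m
  })
  if (any(vapply(planes, is.null, logical(1)))) {
    pages <- tiff::readTIFF(path, all = TRUE)
    planes <- lapply(pages, function(p) matrix(as.numeric(p), nrow(p), ncol(p)))
  }
  out <- lapply(planes, image_plane, pixel_size_um = pixel_size_um,
                channel = channel)
  if (length(out) == 1L) out[[1]] else out
}

#' Read and write analysis tables
#'
#' Thin, deterministic CSV round-trip used for all tabular outputs
#' (granule records, tracks, events, survival records): `write.csv` with
#' `row.names = FALSE`, read back as a tibble. Reruns with identical inputs
#' produce byte-identical files.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_table()`: `path`, invisibly; `read_table_csv()`: a tibble.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  # list-columns (event participants) are serialised as ;-joined ids
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ";"),
                         character(1))
    }
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_csv <- function(path) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Read FRAP traces from CSV
#'
#' Expects columns `time_s`, `roi`, `reference`, `background`, and either a
#' `trace` column separating multiple traces or a single trace per file.
#'
#' @param path CSV path.
#' @param n_pre Pre-bleach frame count attached to each trace.
#' @return A `frap_trace` tibble, or a list of them when a `trace` column
#'   is present.
#' @export
read_frap_traces <- function(path, n_pre) {
  df <- read_table_csv(path)
  need <- c("time_s", "roi", "reference", "background")
  if (!all(need %in% names(df))) {
    abort(paste("FRAP CSV needs columns:", paste(need, collapse = ", ")))
  }
  make <- function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    attr(d, "n_pre") <- as.integer(n_pre)
    class(d) <- c("frap_trace", class(d))
    d
  }
  if ("trace" %in% names(df)) {
    lapply(split(df, df$trace), make)
  } else {
    make(df)
  }
}

#' Write a JSON summary
#'
#' @param x Named list of scalars/vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
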