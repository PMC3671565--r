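#' Read an image stack from TIFF or PNG files
#'
#' Reads a single- or multi-page TIFF, or a sequence of single-image
#' files given as a character vector of paths.  8- and 16-bit integer
#' TIFF pixels are promoted to doubles without rescaling; 32-bit float
#' TIFF samples are returned as stored.  PNG samples are returned on the
#' integer scale of their bit depth.  Multi-channel frames are averaged
#' to one gray channel.
#'
#' @param path Path to a TIFF file, or a character vector of TIFF/PNG
#'   paths forming the stack in order.
#' @return A list of numeric matrices (one per frame) with attribute
#'   `"path"`.  All frames are checked to share one shape; a mismatch is
#'   a format error naming the offending frame.
#' @export
read_image_stack <- function(path) {
  if (!is.character(path) || !length(path)) {
    abort("`path` must be one or more file paths.", class = "sarclen_bad_input")
  }
  missing <- path[!file.exists(path)]
  if (length(missing)) {
    abort(sprintf("file not found: %s", missing[1L]),
          class = "sarclen_format_error")
  }
  frames <- list()
  for (p in path) {
    ext <- tolower(tools::file_ext(p))
    new <- if (ext %in% c("tif", "tiff")) read_tiff_frames(p)
           else if (ext == "png") list(read_png_frame(p))
           else abort(sprintf("unsupported image format: %s", p),
                      class = "sarclen_format_error")
    frames <- c(frames, new)
  }
  for (j in seq_along(frames)) {
    if (!identical(dim(frames[[j]]), dim(frames[[1L]]))) {
      abort(sprintf("frame %d has shape %s but frame 1 has %s.",
                    j, paste(dim(frames[[j]]), collapse = "x"),
                    paste(dim(frames[[1L]]), collapse = "x")),
            class = "sarclen_format_error")
    }
  }
  attr(frames, "path") <- path
  frames
}

read_tiff_frames <- function(p) {
  info <- tiff::readTIFF(p, payload = FALSE, all = TRUE)
  if (is.data.frame(info)) info <- split(info, seq_len(nrow(info)))
  bits <- vapply(info, function(i) as.numeric(i$bits.per.sample[1L]),
                 numeric(1))
  raw_float <- tiff::readTIFF(p, all = TRUE)
  raw_int <- if (any(bits <= 16)) tiff::readTIFF(p, all = TRUE, as.is = TRUE)
             else raw_float
  if (!is.list(raw_float)) raw_float <- list(raw_float)
  if (!is.list(raw_int)) raw_int <- list(raw_int)
  lapply(seq_along(raw_float), function(j) {
    page <- if (bits[min(j, length(bits))] <= 16) raw_int[[j]]
            else raw_float[[j]]
    flatten_gray(page)
  })
}

read_png_frame <- function(p) {
  img <- png::readPNG(p, info = TRUE)
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8
  flatten_gray(img * (2^depth - 1))
}

flatten_gray <- function(page) {
  if (length(dim(page)) == 3L) {
    nch <- min(dim(page)[3L], 3L)          # drop alpha
    page <- apply(page[, , seq_len(nch), drop = FALSE], c(1L, 2L), mean)
  }
  storage.mode(page) <- "double"
  unname(page)
}

#' Write an image stack as a multi-page 32-bit float TIFF
#'
#' @param frames A matrix, list of matrices, or 3-D array.  Values must
#'   lie in `[0, 1]` (the float TIFF convention of the writer) unless
#'   `rescale = TRUE`, in which case they are mapped linearly from their
#'   range.
#' @param path Output path.
#' @param rescale Rescale values to `[0, 1]` before writing.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path, rescale = FALSE) {
  frames <- as_frame_list(frames)
  if (rescale) {
    rng <- range(unlist(lapply(frames, range)))
    span <- if (diff(rng) > 0) diff(rng) else 1
    frames <- lapply(frames, function(f) (f - rng[1L]) / span)
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9) {
    abort("frame values must lie in [0, 1]; use rescale = TRUE.",
          class = "sarclen_bad_input")
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write / read a sarcomere trace as CSV
#'
#' The CSV has one row per frame with columns `time_s`, `sl_px`, `sl_um`,
#' `rate_um_s`, `valid`, `contrast`; invalid frames keep their row with
#' `valid = FALSE` and empty length/rate cells.  Numbers are written with
#' 17 significant digits so a read-back reproduces the trace to the last
#' bit.  Pixel size and frame interval are stored in a `#`-comment
#' header.
#'
#' @param trace A `sarcomere_trace` (see [trace_timeseries()]).
#' @param path Output path.
#' @return `path` invisibly (writer); a `sarcomere_trace` (reader).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sarcomere_trace"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c(
    sprintf("# pixel_size_um=%.17g frame_interval_s=%.17g",
            attr(trace, "pixel_size_um"), attr(trace, "frame_interval_s")),
    "time_s,sl_px,sl_um,rate_um_s,valid,contrast",
    paste(fmt(trace$time_s), fmt(trace$sl_px), fmt(trace$sl_um),
          fmt(trace$rate_um_s), tolower(as.character(trace$valid)),
          ifelse(trace$valid, fmt(trace$contrast), ""), sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- c(pixel_size_um = NA_real_, frame_interval_s = NA_real_)
  if (startsWith(header, "#")) {
    for (key in names(meta)) {
      m <- regmatches(header, regexec(paste0(key, "=([-0-9.eE+]+)"), header))[[1L]]
      if (length(m) == 2L) meta[[key]] <- as.numeric(m[2L])
    }
  }
  # base read.csv: strtod parsing is correctly rounded, so the 17-digit
  # round trip is bit-exact (readr's fast parser can be 1 ulp off)
  raw <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(time_s = "numeric", sl_px = "numeric",
                                        sl_um = "numeric",
                                        rate_um_s = "numeric",
                                        valid = "logical",
                                        contrast = "numeric"))
  out <- as_tibble(raw)
  out$contrast[!out$valid] <- 0
  attr(out, "pixel_size_um") <- meta[["pixel_size_um"]]
  attr(out, "frame_interval_s") <- meta[["frame_interval_s"]]
  class(out) <- c("sarcomere_trace", class(out))
  out
}

run_config_defaults <- function() {
  list(
    input = NULL,
    output = NULL,
    method = "finite",
    mode = "sum",
    pixel_size_um = 0.411,
    frame_interval_s = 0.005,
    s_min = 2,
    s_max = NULL,
    contrast_threshold = 0.1,
    detrend = TRUE,
    period_hint = 4.5,
    window = "hann",
    roi_center_row = NULL,
    roi_center_col = NULL,
    roi_height = 31L,
    roi_width = 54L,
    roi_angle_deg = 0,
    seed = 1L,
    log_level = "info"
  )
}

#' Run configuration for the command-line interface
#'
#' Builds a validated configuration list from defaults, an optional YAML
#' file, and explicit overrides (in that order of increasing priority).
#' Unknown keys are rejected.  Defaults reflect a typical transmission
#' microscopy setup: pixel size 0.411 um, 200 Hz frame rate, 54 x 31 ROI.
#'
#' @param ... Named overrides of configuration keys.
#' @param file Optional path to a YAML configuration file.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- run_config_defaults()
  over <- list(...)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    over <- modifyList(as.list(y), over)
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "sarclen_bad_input")
  }
  cfg <- modifyList(cfg, over, keep.null = TRUE)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) run_config(file = path)

validate_run_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "sarclen_bad_input")
  chk(cfg$method %in% c("finite", "acf", "acf_periodic", "fft_spectrum",
                        "acf_quadratic"), "invalid `method`.")
  chk(cfg$mode %in% c("sum", "per_line_mean"), "invalid `mode`.")
  chk(cfg$pixel_size_um > 0, "`pixel_size_um` must be positive.")
  chk(cfg$frame_interval_s > 0, "`frame_interval_s` must be positive.")
  chk(cfg$s_min > 0, "`s_min` must be positive.")
  chk(is.null(cfg$s_max) || cfg$s_max > cfg$s_min,
      "`s_max` must exceed `s_min`.")
  chk(cfg$contrast_threshold >= 0, "`contrast_threshold` must be >= 0.")
  chk(cfg$period_hint >= 3, "`period_hint` must be >= 3.")
  chk(cfg$window %in% c("hann", "none"), "invalid `window`.")
  invisible(cfg)
}
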