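#' Multi-channel fluorescence field
#'
#' Container for one microscope field: named 2-D intensity rasters of equal
#' shape plus the pixel size.  Required channels are `dna`, `npm1` and
#' `fbl`; additional channels (e.g. `sc35`, `g4`, `ck2a`) are carried
#' through unchanged.
#'
#' @param channels named list of numeric matrices, all the same dimension,
#'   intensities >= 0 on an arbitrary linear scale ([0, 1] by convention).
#' @param pixel_size physical pixel edge length in micrometres per pixel.
#' @param sample_id free-text identifier carried into summaries.
#'
#' @return an object of class `fluor_field`.
#' @export
fluor_field <- function(channels, pixel_size = 0.1, sample_id = "field") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    abort("`channels` must be a named list of matrices.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m),
                 logical(1)))) {
    abort("every channel must be a numeric matrix.")
  }
  if (length(unique(dims)) != 1) abort("all channels must share one shape.")
  if (any(vapply(channels, function(m) any(m < 0), logical(1)))) {
    abort("channel intensities must be non-negative.")
  }
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(channels = channels, pixel_size = pixel_size,
                 sample_id = as.character(sample_id)),
            class = "fluor_field")
}

#' @export
print.fluor_field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<fluor_field '%s'> %d x %d px @ %.3g um/px; channels: %s\n",
              x$sample_id, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.fluor_field <- function(x) dim(x$channels[[1]])

#' Write / read a field as TIFF files with a channel-map sidecar
#'
#' Each channel is written as one 16-bit grayscale TIFF
#' (`<sample_id>_<channel>.tif`, intensities clipped to [0, 1]) next to a
#' plain-text `channel_map.txt` sidecar listing channel name, file name and
#' the pixel size.  `read_field()` inverts the layout.
#'
#' @param field a [fluor_field()].
#' @param dir output directory (created if absent).
#' @param truth optional truth table (e.g. from [generate_field()]); written
#'   as `<sample_id>_truth.tsv` alongside the images.
#' @return `write_field()` returns `dir` invisibly; `read_field()` returns a
#'   `fluor_field`.
#' @export
write_field <- function(field, dir, truth = NULL) {
  stopifnot(inherits(field, "fluor_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ch in names(field$channels)) {
    fn <- sprintf("%s_%s.tif", field$sample_id, ch)
    img <- pmin(pmax(field$channels[[ch]], 0), 1)
    tiff::writeTIFF(img, file.path(dir, fn), bits.per.sample = 16)
    files[ch] <- fn
  }
  map <- c(sprintf("# pixel_size_um\t%.10g", field$pixel_size),
           sprintf("# sample_id\t%s", field$sample_id),
           sprintf("%s\t%s", names(files), files))
  writeLines(map, file.path(dir, "channel_map.txt"))
  if (!is.null(truth)) {
    readr::write_tsv(truth,
                     file.path(dir, sprintf("%s_truth.tsv", field$sample_id)))
  }
  invisible(dir)
}

#' @rdname write_field
#' @export
read_field <- function(dir) {
  map_path <- file.path(dir, "channel_map.txt")
  if (!file.exists(map_path)) abort("no channel_map.txt found in `dir`.")
  lines <- readLines(map_path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (length(hit)) sub(".*\t", "", hit[1]) else default
  }
  pixel_size <- as.numeric(get_meta("pixel_size_um", "0.1"))
  sample_id <- get_meta("sample_id", "field")
  parts <- strsplit(body, "\t", fixed = TRUE)
  channels <- lapply(parts, function(p) {
    m <- tiff::readTIFF(file.path(dir, p[2]))
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  names(channels) <- vapply(parts, `[`, character(1), 1)
  fluor_field(channels, pixel_size = pixel_size, sample_id = sample_id)
}
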