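## On-disk layout: one single-plane grayscale TIFF per (well, field, channel)
## named r{RR}c{CC}f{FF}-{channel}.tiff (RR = row number A=01, zero-padded),
## plus platemap.json. Pixels are stored as 16-bit unsigned and converted to
## doubles on load so all downstream math is in reals.

field_key <- function(well, field_index) sprintf("%s_f%02d", well, field_index)

image_file_name <- function(row, col, field_index, channel) {
  sprintf("r%02dc%02df%02d-%s.tiff", match(row, LETTERS[1:16]), col,
          field_index, channel)
}

#' Construct a plate bundle
#'
#' A plate bundle holds a [plate_map()] together with all field images of
#' the plate, indexed by well and field. Every (well, field) must carry
#' exactly the four channels of [cp_channels()], all with identical grid
#' shape.
#'
#' @param platemap A [plate_map()] object.
#' @param images Named list keyed `"<well>_f<FF>"`; each element a named
#'   list of four numeric matrices, one per channel.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class `PlateBundle`.
#' @export
plate_bundle <- function(platemap, images, pixel_size_um) {
  stopifnot(inherits(platemap, "PlateMap"), is.list(images), pixel_size_um > 0)
  for (key in names(images)) {
    chans <- images[[key]]
    if (!setequal(names(chans), CP_CHANNELS)) {
      missing_ch <- setdiff(CP_CHANNELS, names(chans))
      extra_ch <- setdiff(names(chans), CP_CHANNELS)
      stop("field ", key,
           if (length(missing_ch)) paste0(": missing channel(s) ",
                                          paste(missing_ch, collapse = ", ")),
           if (length(extra_ch)) paste0(": unknown channel(s) ",
                                        paste(extra_ch, collapse = ", ")))
    }
    dims <- vapply(chans, dim, integer(2))
    if (any(dims != dims[, 1]))
      stop("field ", key, ": channel grids differ in shape")
  }
  structure(list(platemap = platemap, images = images,
                 pixel_size_um = pixel_size_um),
            class = "PlateBundle")
}

#' @export
print.PlateBundle <- function(x, ...) {
  cat(sprintf("PlateBundle '%s': %d field(s) x 4 channels, pixel %.3g um\n",
              x$platemap$plate_id, length(x$images), x$pixel_size_um))
  invisible(x)
}

#' List the (well, field) pairs of a plate bundle
#'
#' @param bundle A [plate_bundle()].
#' @return `data.frame` with columns `key`, `well`, `field`.
#' @export
bundle_fields <- function(bundle) {
  stopifnot(inherits(bundle, "PlateBundle"))
  keys <- names(bundle$images)
  data.frame(key = keys,
             well = sub("_f[0-9]+$", "", keys),
             field = as.integer(sub("^.*_f", "", keys)))
}

#' Fetch one channel grid from a plate bundle
#'
#' @param bundle A [plate_bundle()].
#' @param well Well address.
#' @param field Field index (0-based).
#' @param channel One of [cp_channels()].
#' @return A [field_image()].
#' @export
get_field_image <- function(bundle, well, field, channel) {
  key <- field_key(well, field)
  if (is.null(bundle$images[[key]]))
    stop("no such field in bundle: ", key)
  field_image(well, field, channel, bundle$images[[key]][[channel]],
              bundle$pixel_size_um)
}

#' Write a plate bundle to disk
#'
#' Writes one 16-bit grayscale TIFF per (well, field, channel) plus
#' `platemap.json` into `dir`. Intensities are clipped to the 16-bit range
#' and rounded; the simulator emits integer-valued grids so the round trip
#' through [read_plate()] is bit-identical.
#'
#' @param bundle A [plate_bundle()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(bundle, dir) {
  stopifnot(inherits(bundle, "PlateBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_plate_map(bundle$platemap, file.path(dir, "platemap.json"))
  jsonlite::write_json(list(pixel_size_um = bundle$pixel_size_um),
                       file.path(dir, "plate.json"), auto_unbox = TRUE,
                       digits = NA)
  fl <- bundle_fields(bundle)
  wl <- bundle$platemap$wells
  for (i in seq_len(nrow(fl))) {
    w <- wl[wl$well == fl$well[i], ]
    for (ch in CP_CHANNELS) {
      px <- bundle$images[[fl$key[i]]][[ch]]
      px <- round(pmin(pmax(px, 0), 65535))
      tiff::writeTIFF(px / 65535, file.path(dir, image_file_name(
        w$row, w$col, fl$field[i], ch)), bits.per.sample = 16,
        compression = "none")
    }
  }
  invisible(dir)
}

#' Read a plate from disk
#'
#' Reads `platemap.json` and every field TIFF under the documented naming
#' scheme. Each (well, field) must provide exactly the four channels;
#' missing or extra channels are a hard error naming the field.
#'
#' @param image_dir Directory holding the TIFFs.
#' @param platemap_file Path to the plate map JSON (defaults to
#'   `platemap.json` inside `image_dir`).
#' @return A [plate_bundle()].
#' @export
read_plate <- function(image_dir,
                       platemap_file = file.path(image_dir, "platemap.json")) {
  if (!dir.exists(image_dir)) stop("image directory not found: ", image_dir)
  platemap <- read_plate_map(platemap_file)
  meta_path <- file.path(image_dir, "plate.json")
  pixel_size_um <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$pixel_size_um else 1
  files <- list.files(image_dir, pattern = "^r[0-9]{2}c[0-9]{2}f[0-9]{2}-.*\\.tiff$")
  if (!length(files)) stop("no field TIFFs found in ", image_dir)
  info <- regmatches(files, regexec(
    "^r([0-9]{2})c([0-9]{2})f([0-9]{2})-(.*)\\.tiff$", files))
  images <- list()
  for (i in seq_along(files)) {
    m <- info[[i]]
    row <- LETTERS[as.integer(m[2])]
    well <- well_address(row, as.integer(m[3]))
    fidx <- as.integer(m[4])
    channel <- m[5]
    if (!channel %in% CP_CHANNELS)
      stop("file ", files[i], ": unknown channel '", channel, "'")
    px <- tiff::readTIFF(file.path(image_dir, files[i]))
    if (length(dim(px)) == 3L) px <- px[, , 1]
    key <- field_key(well, fidx)
    images[[key]][[channel]] <- round(px * 65535)
  }
  for (key in names(images)) {
    miss <- setdiff(CP_CHANNELS, names(images[[key]]))
    if (length(miss))
      stop("field ", key, ": missing channel(s) ", paste(miss, collapse = ", "))
    images[[key]] <- images[[key]][CP_CHANNELS]  # canonical channel order
  }
  plate_bundle(platemap, images, pixel_size_um)
}

#' Write / read a tabular result
#'
#' CSV or parquet writer for feature tables and well-level results.
#' Re-reading reproduces values to full stored precision and preserves
#' column order.
#'
#' @param table Nonempty `data.frame`.
#' @param path Output path; the parent directory must exist.
#' @param format `"csv"` or `"parquet"` (parquet requires the `arrow`
#'   package).
#' @return `read_table_file` returns a `data.frame`; `write_table_file`
#'   returns `path` invisibly.
#' @export
write_table_file <- function(table, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L || ncol(table) == 0L) stop("refusing to write an empty table")
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  if (format == "csv") {
    ## full double precision via 17 significant digits
    tab <- table
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("parquet output requires the 'arrow' package")
    arrow::write_parquet(table, path)
  }
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    utils::read.csv(path, check.names = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("parquet input requires the 'arrow' package")
    as.data.frame(arrow::read_parquet(path))
  }
}
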