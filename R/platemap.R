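#' Construct a plate map
#'
#' A plate map describes one 384-well plate: its identifier, imaging
#' magnification, fields per well, and one row per used well giving the
#' treatment label, dose, role (`vehicle` / `treatment` / `untreated`) and
#' replicate group. Vehicle wells carry the DMSO solvent control that every
#' normalization step (roundness Z-score, %M2-%M1 centering) is anchored to.
#'
#' @param plate_id Plate identifier string.
#' @param wells A `data.frame` with columns `row` (letter A-P), `col`
#'   (integer 1-24), `treatment`, `dose`, `dose_unit`, `role`,
#'   `replicate_group`. Missing `dose`/`dose_unit`/`replicate_group` columns
#'   are filled with defaults (0, `"uM"`, the treatment label).
#' @param magnification `"20x"` or `"40x"`.
#' @param fields_per_well Number of imaged fields per well (>= 1). The assay
#'   convention is a minimum of 5 fields at 20x and 10 fields at 40x.
#' @return An object of class `PlateMap`.
#' @examples
#' pm <- plate_map("P1", data.frame(
#'   row = c("A", "A"), col = 1:2,
#'   treatment = c("DMSO", "drugX"),
#'   role = c("vehicle", "treatment")))
#' @export
plate_map <- function(plate_id, wells, magnification = c("20x", "40x"),
                      fields_per_well = NULL) {
  magnification <- match.arg(magnification)
  if (is.null(fields_per_well))
    fields_per_well <- if (magnification == "40x") 10L else 5L
  fields_per_well <- as.integer(fields_per_well)
  stopifnot(is.character(plate_id), length(plate_id) == 1L,
            fields_per_well >= 1L, is.data.frame(wells), nrow(wells) >= 1L)
  need <- c("row", "col", "treatment", "role")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop("plate map is missing column(s): ", paste(miss, collapse = ", "))
  if (!"dose" %in% names(wells)) wells$dose <- 0
  if (!"dose_unit" %in% names(wells)) wells$dose_unit <- "uM"
  if (!"replicate_group" %in% names(wells))
    wells$replicate_group <- wells$treatment
  wells$row <- as.character(wells$row)
  wells$col <- as.integer(wells$col)
  wells$role <- as.character(wells$role)
  wells$treatment <- as.character(wells$treatment)
  if (!all(wells$row %in% LETTERS[1:16]))
    stop("well rows must be letters A-P (384-well bounds)")
  if (any(wells$col < 1L | wells$col > 24L))
    stop("well columns must be 1-24 (384-well bounds)")
  if (!all(wells$role %in% c("vehicle", "treatment", "untreated")))
    stop("well role must be vehicle, treatment or untreated")
  if (any(wells$dose < 0)) stop("doses must be nonnegative")
  bad <- wells$role == "vehicle" & wells$treatment != "DMSO"
  if (any(bad))
    stop("vehicle wells must carry treatment label 'DMSO' (wells: ",
         paste(well_address(wells$row[bad], wells$col[bad]), collapse = ", "), ")")
  wells$well <- well_address(wells$row, wells$col)
  if (anyDuplicated(wells$well))
    stop("duplicate well address(es): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  rownames(wells) <- NULL
  structure(list(plate_id = plate_id, magnification = magnification,
                 fields_per_well = fields_per_well,
                 wells = wells[, c("well", "row", "col", "treatment", "dose",
                                   "dose_unit", "role", "replicate_group")]),
            class = "PlateMap")
}

#' @export
print.PlateMap <- function(x, ...) {
  cat(sprintf("PlateMap '%s': %d wells, %s, %d field(s)/well\n",
              x$plate_id, nrow(x$wells), x$magnification, x$fields_per_well))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$wells$role)),
                                table(x$wells$role)), collapse = ", "), "\n")
  invisible(x)
}

#' Vehicle (DMSO) wells of a plate map
#'
#' @param platemap A [plate_map()] object.
#' @return Character vector of well addresses with role `vehicle`.
#' @export
vehicle_wells <- function(platemap) {
  stopifnot(inherits(platemap, "PlateMap"))
  platemap$wells$well[platemap$wells$role == "vehicle"]
}

#' Write / read a plate map as JSON
#'
#' @param platemap A [plate_map()] object.
#' @param path File path of the JSON plate map.
#' @return `read_plate_map` returns a `PlateMap`; `write_plate_map` returns
#'   `path` invisibly.
#' @export
write_plate_map <- function(platemap, path) {
  stopifnot(inherits(platemap, "PlateMap"))
  obj <- list(plate_id = platemap$plate_id,
              magnification = platemap$magnification,
              fields_per_well = platemap$fields_per_well,
              wells = platemap$wells[, c("row", "col", "treatment", "dose",
                                         "dose_unit", "role", "replicate_group")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed plate map JSON '", path,
                                           "': ", conditionMessage(e)))
  for (f in c("plate_id", "magnification", "fields_per_well", "wells"))
    if (is.null(obj[[f]])) stop("plate map '", path, "' lacks field '", f, "'")
  plate_map(obj$plate_id, as.data.frame(obj$wells),
            magnification = obj$magnification,
            fields_per_well = obj$fields_per_well)
}

#' Construct a field image
#'
#' One channel's 2D intensity grid for one well/field. All channels of a
#' field must share the same grid shape; intensities are nonnegative reals
#' (16-bit camera counts converted to doubles on load).
#'
#' @param well Well address such as `"B03"`.
#' @param field_index Field index (0-based integer).
#' @param channel One of [cp_channels()].
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class `FieldImage`.
#' @export
field_image <- function(well, field_index, channel, pixels, pixel_size_um) {
  if (!channel %in% CP_CHANNELS)
    stop("unknown channel '", channel, "'; must be one of ",
         paste(CP_CHANNELS, collapse = ", "))
  parse_well_address(well)
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_size_um > 0,
            field_index >= 0)
  if (any(pixels < 0)) stop("pixel intensities must be nonnegative")
  structure(list(well = well, field_index = as.integer(field_index),
                 channel = channel, pixels = pixels,
                 pixel_size_um = pixel_size_um),
            class = "FieldImage")
}

#' @export
print.FieldImage <- function(x, ...) {
  cat(sprintf("FieldImage %s f%02d %s: %dx%d px (%.3g um/px)\n", x$well,
              x$field_index, x$channel, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um))
  invisible(x)
}
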