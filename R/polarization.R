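## The cell-roundness read-out: per-well mean roundness, the Z-score of
## each condition against the DMSO vehicle wells of the same plate
## (Z > 0: rounded, M1(-like); Z < 0: elongated, M2(-like)), and the
## cell-count toxicity flag.

#' Per-well mean cell roundness
#'
#' Arithmetic mean of the full-cell roundness feature over retained cells
#' per well, with the nucleus-count cell number.
#'
#' @param cell_table A feature table containing `morph_cell_roundness`
#'   (e.g. from [extract_features()]), or any `data.frame` with columns
#'   `well` and the roundness column.
#' @param roundness_col Name of the roundness column.
#' @return `data.frame` with columns `well`, `n_cells`, `mean_roundness`.
#' @export
well_mean_roundness <- function(cell_table,
                                roundness_col = "morph_cell_roundness") {
  stopifnot(is.data.frame(cell_table))
  if (!roundness_col %in% names(cell_table))
    stop("cell table lacks the roundness column '", roundness_col, "'")
  wells <- unique(cell_table$well)
  out <- data.frame(
    well = wells,
    n_cells = vapply(wells, function(w) sum(cell_table$well == w), integer(1)),
    mean_roundness = vapply(wells, function(w)
      mean(cell_table[[roundness_col]][cell_table$well == w]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cell-roundness Z-score versus DMSO vehicle wells
#'
#' Z = (well mean roundness - mean over vehicle-well means) / sample sd
#' over vehicle-well means. Vehicle wells are scored against themselves,
#' so their Z-scores have mean 0 and sample sd 1 exactly. A positive Z
#' indicates a more rounded (M1-like) morphology, a negative Z a more
#' elongated (M2-like) one.
#'
#' @param well_stats Output of [well_mean_roundness()] (wells with 0 cells
#'   are excluded and flagged).
#' @param platemap The [plate_map()] identifying vehicle wells; at least
#'   two vehicle wells with cells are required.
#' @param toxicity_threshold Fraction of the vehicle median cell count
#'   below which a well is flagged as toxic (default 0.5).
#' @return `data.frame` with columns `well`, `n_cells`, `mean_roundness`,
#'   `zscore`, `toxicity_flag`.
#' @export
roundness_zscore <- function(well_stats, platemap, toxicity_threshold = 0.5) {
  stopifnot(inherits(platemap, "PlateMap"))
  keep <- well_stats$n_cells > 0
  dropped <- well_stats$well[!keep]
  if (length(dropped))
    cp_log("zscore", "excluding empty well(s): ",
           paste(dropped, collapse = ", "))
  ws <- well_stats[keep, , drop = FALSE]
  veh <- intersect(vehicle_wells(platemap), ws$well)
  if (length(veh) < 2L)
    stop("plate ", platemap$plate_id,
         ": need >= 2 vehicle wells with cells for the Z-score (have ",
         length(veh), ")")
  vm <- ws$mean_roundness[match(veh, ws$well)]
  mu <- mean(vm)
  sdv <- stats::sd(vm)
  if (sdv == 0)
    stop("plate ", platemap$plate_id,
         ": vehicle-well roundness means have zero spread")
  ws$zscore <- (ws$mean_roundness - mu) / sdv
  ws$toxicity_flag <- toxicity_flag(ws, veh, toxicity_threshold)
  rownames(ws) <- NULL
  ws
}

#' Cell-count toxicity flag
#'
#' Flags wells whose cell count falls below `threshold_fraction` times the
#' median vehicle-well cell count — the decreased-nucleus-count signature
#' of cytotoxic conditions.
#'
#' @param well_stats `data.frame` with columns `well` and `n_cells`.
#' @param vehicle Character vector of vehicle well addresses.
#' @param threshold_fraction Default 0.5.
#' @return Logical vector aligned with `well_stats` rows.
#' @export
toxicity_flag <- function(well_stats, vehicle, threshold_fraction = 0.5) {
  veh_n <- well_stats$n_cells[well_stats$well %in% vehicle]
  if (!length(veh_n)) stop("no vehicle wells present for toxicity flagging")
  well_stats$n_cells < threshold_fraction * stats::median(veh_n)
}
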