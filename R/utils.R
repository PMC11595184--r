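#' @keywords internal
"_PACKAGE"

## Channel vocabulary is closed: these are the four dyes the feature-based
## analysis uses (nucleus, ER/cytoplasm, actin/WGA-like, mitochondria-like).
CP_CHANNELS <- c("Hoechst33342", "Alexa488", "Alexa568", "Alexa647")
CP_REGIONS  <- c("nucleus", "cytoplasm", "cell")
CP_CLASSES  <- c("M0", "M1like", "M2like", "dead")

#' Channel names used throughout the pipeline
#'
#' Returns the closed set of channel names (`Hoechst33342`, `Alexa488`,
#' `Alexa568`, `Alexa647`). Any other channel name is rejected at parse time.
#'
#' @return Character vector of length 4.
#' @export
cp_channels <- function() CP_CHANNELS

#' Cell polarization class labels
#'
#' @return Character vector `c("M0", "M1like", "M2like", "dead")`.
#' @export
cp_classes <- function() CP_CLASSES

## Deterministic 31-bit string hash (java-style), used to derive stage/well
## seeds from a single run seed without seed bookkeeping.
str_hash31 <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

## Derive a child seed from a base seed and a label; stays below 2^31.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 + str_hash31(label)) %% 2147483647)
}

## Evaluate `expr` with a local RNG state so library code never disturbs the
## caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Structured stage logging to stderr with timing.
cp_log <- function(stage, ..., t0 = NULL) {
  msg <- paste0(...)
  if (!is.null(t0)) {
    dt <- round(as.numeric(Sys.time()) - t0, 2)
    msg <- sprintf("%s (%.2fs)", msg, dt)
  }
  message(sprintf("[cellpaintr:%s] %s", stage, msg))
  invisible(NULL)
}

## Well address helpers: "B03" <-> row letter A-P, column 1-24 (384-well).
well_address <- function(row, col) sprintf("%s%02d", row, as.integer(col))

parse_well_address <- function(address) {
  stopifnot(grepl("^[A-P][0-9]{1,2}$", address))
  list(row = substr(address, 1, 1),
       col = as.integer(substr(address, 2, nchar(address))))
}

pos_part <- function(x) pmax(x, 0)
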