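# All internal quantities are SI: hectares, cubic metres, metric tons, USD.
# Field data quoted per acre or in acre-feet are converted once, on entry.

ACRE_TO_HA <- 0.40469
ACRE_FOOT_TO_M3 <- 1233.48
ACRE_INCH_TO_M3 <- ACRE_FOOT_TO_M3 / 12

#' Convert acres to hectares
#'
#' @param x areas in acres.
#' @return areas in hectares (1 acre = 0.40469 ha).
#' @export
acres_to_ha <- function(x) x * ACRE_TO_HA

#' Convert a per-acre water volume to a per-hectare volume
#'
#' Water allotments for surface irrigation are customarily quoted as a depth
#' over an acre (acre-feet per acre). Internally every per-area water
#' quantity is cubic metres per hectare.
#'
#' @param x volumes in cubic metres per acre.
#' @return volumes in cubic metres per hectare.
#' @export
per_acre_to_per_ha <- function(x) x / ACRE_TO_HA

#' Convert acre-feet to cubic metres
#'
#' @param x volumes in acre-feet.
#' @return volumes in cubic metres (1 acre-foot = 1233.48 m3).
#' @export
acre_feet_to_m3 <- function(x) x * ACRE_FOOT_TO_M3

# Evaluate `code` under a reproducible, self-contained RNG stream.
# The caller's .Random.seed is untouched, so generation is a pure function
# of the supplied seed and never perturbs (or depends on) global RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
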