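#' @keywords internal
"_PACKAGE"

# mg/dL per mmol/L; all index math is done in mg/dL, the unit in which
# LBGI/HBGI/GVP were originally published.
MGDL_PER_MMOL <- 18.018

# Consensus glycemic range thresholds, exact products of the mmol/L
# definitions (3.9, 10.0, 13.9, 3.0 mmol/L) so the TIR/TAR/TBR partition
# identity holds exactly.
AGP_THRESHOLDS <- list(
  tbr  = 3.9  * MGDL_PER_MMOL,  # 70.2702  mg/dL
  tsbr = 3.0  * MGDL_PER_MMOL,  # 54.054   mg/dL
  tar  = 10.0 * MGDL_PER_MMOL,  # 180.18   mg/dL
  tsar = 13.9 * MGDL_PER_MMOL   # 250.4502 mg/dL
)

# Typical CGM sensor reporting range, mg/dL.
SENSOR_RANGE <- c(39, 400)

SLOTS_PER_DAY <- 96L
SLOT_MINUTES  <- 15L

#' Convert glucose between mmol/L and mg/dL
#'
#' Uses the molar mass based factor 18.018 mg/dL per mmol/L. The round trip
#' mmol -> mg/dL -> mmol is exact to floating point.
#'
#' @param x numeric vector of glucose values.
#' @return numeric vector in the target unit.
#' @examples
#' mmol_to_mgdl(5.55)   # ~100 mg/dL
#' mgdl_to_mmol(180.18) # 10 mmol/L
#' @export
mmol_to_mgdl <- function(x) x * MGDL_PER_MMOL

#' @rdname mmol_to_mgdl
#' @export
mgdl_to_mmol <- function(x) x / MGDL_PER_MMOL

# Run expr with a temporary RNG state seeded at `seed`; the caller's RNG
# state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed below 2^31 from a root seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483629)
}
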