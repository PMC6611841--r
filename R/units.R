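# Unit conventions: all internal computation is SI (Pa, m, s, kg).
# mmHg, mL/s and uL appear only at I/O boundaries.

#: Pa per mmHg; single fixed conversion constant used package-wide
MMHG_PA <- 133.322

#' Convert between mmHg and Pa
#'
#' All internal computation in aqueflow is in SI units; pressures cross the
#' package boundary in mmHg (the clinical convention for ICP). The conversion
#' constant is fixed at 133.322 Pa/mmHg.
#'
#' @param x numeric vector of pressures (or pressure gradients, in which case
#'   the conversion applies to the pressure part only, e.g. mmHg/m to Pa/m).
#' @return numeric vector in the other unit.
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA
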