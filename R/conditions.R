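#' Exchange conditions (pH/pD and temperature)
#'
#' Bundles the solution conditions under which amide exchange proceeds.
#' Deuterated buffers are usually reported as a pH-meter reading; the glass
#' electrode under-reads pD by about 0.4 units, so by default the stated pH is
#' converted to pD as `pD = pH + 0.4`. Pass `pD_corrected = TRUE` if the value
#' supplied already is a pD.
#'
#' @param pH Numeric scalar, pH-meter reading (or pD, see `pD_corrected`).
#' @param temperature Numeric scalar, kelvin.
#' @param label Free-text role of the condition set, conventionally
#'   `"labeling"` or `"quench"`.
#' @param pD_corrected Logical; if `TRUE`, `pH` is taken as pD unchanged.
#'
#' @return An object of class `hdx_conditions` with elements `pH_meter`, `pD`,
#'   `temperature` and `label`.
#' @examples
#' exchange_conditions(7.0, 298.15, "labeling")
#' exchange_conditions(2.5, 273.15, "quench")
#' @export
exchange_conditions <- function(pH, temperature, label = "labeling",
                                pD_corrected = FALSE) {
  stopifnot(is.numeric(pH), length(pH) == 1L,
            is.numeric(temperature), length(temperature) == 1L)
  if (!(pH > 0 && pH < 14)) .stop_pos("pH must lie strictly between 0 and 14")
  if (!(temperature > 0)) .stop_pos("temperature must be positive (kelvin)")
  out <- list(pH_meter = pH,
              pD = if (pD_corrected) pH else pH + 0.4,
              temperature = temperature,
              label = as.character(label)[1])
  class(out) <- "hdx_conditions"
  out
}

#' @export
print.hdx_conditions <- function(x, ...) {
  cat(sprintf("<hdx_conditions '%s'> pD %.2f (meter %.2f), %.2f K\n",
              x$label, x$pD, x$pH_meter, x$temperature))
  invisible(x)
}

.as_conditions <- function(x) {
  if (!inherits(x, "hdx_conditions"))
    .stop_pos("expected an `hdx_conditions` object (see exchange_conditions())")
  x
}
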