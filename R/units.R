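#' Unit converters
#'
#' All computations in the package use SI units (A, V, s, C).  These helpers
#' convert between SI and the units conventional in the synaptic physiology
#' literature (pA, nA, mV, ms, pC, fC).  Each `x_to_*` function takes SI and
#' returns the conventional unit; the bare functions (`pA()`, ...) take the
#' conventional unit and return SI.
#'
#' @param x Numeric.
#' @return Numeric, converted.
#' @name units
#' @examples
#' pA(20)            # 2e-11 A
#' to_pA(2e-11)      # 20
NULL

#' @rdname units
#' @export
pA <- function(x) x * 1e-12
#' @rdname units
#' @export
nA <- function(x) x * 1e-9
#' @rdname units
#' @export
mV <- function(x) x * 1e-3
#' @rdname units
#' @export
ms <- function(x) x * 1e-3
#' @rdname units
#' @export
pC <- function(x) x * 1e-12
#' @rdname units
#' @export
fC <- function(x) x * 1e-15
#' @rdname units
#' @export
to_pA <- function(x) x * 1e12
#' @rdname units
#' @export
to_nA <- function(x) x * 1e9
#' @rdname units
#' @export
to_mV <- function(x) x * 1e3
#' @rdname units
#' @export
to_ms <- function(x) x * 1e3
#' @rdname units
#' @export
to_pC <- function(x) x * 1e12
#' @rdname units
#' @export
to_fC <- function(x) x * 1e15
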