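#' Physical constants and unit conversions
#'
#' All coordinates in this package are right-handed Cartesian in nanometres;
#' DNA lengths convert between nm and base pairs through the canonical rise
#' of B-DNA, 0.34 nm/bp. The nucleosome core is the 146-bp particle; the
#' mesoscale linker-DNA bead subsumes 3.0 nm of DNA, i.e. 8.8235 bp.
#'
#' @name constants
NULL

# single definition site for every unit conversion (see nm_to_bp/bp_to_nm)
.NM_PER_BP <- 0.34
.CORE_BP <- 146
.BEAD_NM <- 3.0
.BEAD_BP <- .BEAD_NM / .NM_PER_BP # 8.8235...

#' Convert between nanometres and base pairs
#'
#' Uses 0.34 nm per DNA base pair throughout the package.
#'
#' @param nm,bp numeric vectors of lengths.
#' @return numeric vector of converted lengths.
#' @examples
#' nm_to_bp(3.4) # 10
#' bp_to_nm(10)  # 3.4
#' @export
nm_to_bp <- function(nm) nm / .NM_PER_BP

#' @rdname nm_to_bp
#' @export
bp_to_nm <- function(bp) bp * .NM_PER_BP

#' Nucleosome core DNA length in base pairs
#'
#' The canonical 146-bp core (crystallographic nucleosome core particle),
#' the reference from which constrained core length C and nucleosome repeat
#' length are computed.
#' @return integer scalar, 146.
#' @export
core_length_bp <- function() .CORE_BP
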