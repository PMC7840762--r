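#' Vacuum permittivity (F/m)
#'
#' The electric constant \eqn{\varepsilon_0 = 8.8541878128\times 10^{-12}}
#' farad per metre, used to convert relative permittivities to absolute ones
#' in the Maxwell-stress and dipole-force expressions.
#'
#' @format Length-one numeric, farad per metre.
#' @export
EPS0 <- 8.8541878128e-12
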