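#' Parameters of the theoretical ethanol-yield conversion
#'
#' The stoichiometric glucose-to-ethanol conversion factor 0.511
#' (NREL standard), the area factor converting biomass from kg/m2 to kg/ha,
#' and the output divisor. The conversion factor is overridable for
#' sensitivity analyses but defaults to the standard value.
#'
#' @param conversionFactor dimensionless glucose-to-ethanol factor.
#' @param areaFactor m2 per ha (kg/m2 -> kg/ha).
#' @param outputDivisor divisor applied to the product.
#' @return list of the three parameters.
#' @export
ethanolParams <- function(conversionFactor = 0.511, areaFactor = 10000,
                          outputDivisor = 1000) {
  stopifnot(conversionFactor > 0, areaFactor > 0, outputDivisor > 0)
  list(conversionFactor = conversionFactor, areaFactor = areaFactor,
       outputDivisor = outputDivisor)
}

#' Theoretical ethanol yield from biomass and sugar release
#'
#' Computes E = S x 0.511 x (W x 10000) / 1000 for sugar release S in ul
#' glucose per mg straw and total biomass dry weight W in kg/m2 (converted
#' to kg/ha by the area factor). The value is reported on the m3/ha scale
#' on which species and accession yields are conventionally tabulated for
#' this formula; the raw formula label would read L/ha, an inconsistency of
#' the source equation that is documented rather than resolved here.
#'
#' Bilinear in its two inputs: E(aS, bW) = ab E(S, W).
#'
#' @param sugarRelease numeric vector, ul/mg, non-negative.
#' @param biomass numeric vector, kg/m2, non-negative.
#' @param params parameter list from [ethanolParams()].
#' @return numeric vector, theoretical ethanol yield in m3/ha.
#' @examples
#' theoreticalEthanolYield(1.16, 0.71)  # 4.21 to two decimals
#' @export
theoreticalEthanolYield <- function(sugarRelease, biomass,
                                    params = ethanolParams()) {
  if (any(sugarRelease < 0, na.rm = TRUE))
    stop("sugarRelease must be non-negative")
  if (any(biomass < 0, na.rm = TRUE))
    stop("biomass must be non-negative")
  sugarRelease * params$conversionFactor *
    (biomass * params$areaFactor) / params$outputDivisor
}
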