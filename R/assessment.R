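## Map-quality metrics, cost-benefit model and nutrient-runoff risk.
## Convention: positive = healthy. A false positive is a truly unhealthy
## zone classified healthy (it goes untreated and loses yield); a false
## negative is a truly healthy zone classified unhealthy (it is treated
## unnecessarily, the runoff-risk event).

#' Confusion counts between a predicted and a true health map
#'
#' @param predicted,truth Complete integer label matrices of equal shape
#'   (1 healthy, 0 unhealthy).
#' @return Named integer vector with elements \code{tp} (healthy as
#'   healthy), \code{tn} (unhealthy as unhealthy), \code{fp} (unhealthy as
#'   healthy: missed, untreated), \code{fn} (healthy as unhealthy:
#'   overtreated).
#' @export
confusionCounts <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)))
    stop("predicted and truth maps differ in shape")
  if (any(is.na(predicted)) || any(is.na(truth)))
    stop("maps must be complete")
  c(tp = sum(predicted == 1L & truth == 1L),
    tn = sum(predicted == 0L & truth == 0L),
    fp = sum(predicted == 1L & truth == 0L),
    fn = sum(predicted == 0L & truth == 1L))
}

#' Accuracy, precision and recall of a health map
#'
#' Positive recall is the fraction of truly healthy zones labeled healthy;
#' negative recall the fraction of truly unhealthy zones labeled unhealthy.
#' Metrics with a zero denominator are reported as NA, never silently 0.
#'
#' @param counts Confusion counts from \code{\link{confusionCounts}}.
#' @return Named numeric vector: \code{accuracy}, \code{posPrecision},
#'   \code{posRecall}, \code{negPrecision}, \code{negRecall}.
#' @export
mapMetrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    posPrecision = rat(tp, tp + fp),
    posRecall = rat(tp, tp + fn),
    negPrecision = rat(tn, tn + fn),
    negRecall = rat(tn, tn + fp))
}

#' Construct economic parameters
#'
#' Defaults are 2018-season corn economics: $3.8/bushel at 200 bushels per
#' acre ($763.8/acre revenue), $130/acre fertilizer, 4.3 m2 management
#' zones, $10/h unskilled and $20/h skilled labor, and 0.33 h of flight per
#' charge (the mid-range of a 15-25 min commodity-UAS battery).
#'
#' @param revenuePerAcre,fertilizerPerAcre USD per acre.
#' @param zoneAreaM2 Zone area in square metres.
#' @param m2PerAcre Square metres per acre.
#' @param wageUnskilled,wageSkilled USD per hour.
#' @param hoursPerCharge Flight hours per battery charge.
#' @return An \linkS4class{EconParams}.
#' @export
econParams <- function(revenuePerAcre = 763.8, fertilizerPerAcre = 130,
                       zoneAreaM2 = 4.3, m2PerAcre = 4046.86,
                       wageUnskilled = 10, wageSkilled = 20,
                       hoursPerCharge = 0.33) {
  new("EconParams", revenuePerAcre = revenuePerAcre,
      fertilizerPerAcre = fertilizerPerAcre, zoneAreaM2 = zoneAreaM2,
      m2PerAcre = m2PerAcre, wageUnskilled = wageUnskilled,
      wageSkilled = wageSkilled, hoursPerCharge = hoursPerCharge)
}

setMethod("show", "EconParams", function(object) {
  pz <- perZoneConstants(object)
  cat("EconParams: revenue $", object@revenuePerAcre, "/acre, fertilizer $",
      object@fertilizerPerAcre, "/acre |", object@zoneAreaM2,
      "m2 zones -> $", pz[["revenuePerZone"]], "and $",
      pz[["fertilizerPerZone"]], "per zone\n")
})

#' Per-zone revenue and fertilizer constants
#'
#' Converts per-acre constants to per-zone constants by area
#' (\code{perAcre * zoneArea / m2PerAcre}), rounded to one decimal: $0.8
#' revenue and $0.1 fertilizer per 4.3 m2 zone under the defaults. Their
#' ratio of 8 is what makes a missed unhealthy zone eight times as costly
#' as an overtreated healthy one.
#'
#' @param params An \linkS4class{EconParams}.
#' @return Named numeric vector \code{revenuePerZone},
#'   \code{fertilizerPerZone}.
#' @export
perZoneConstants <- function(params = econParams()) {
  f <- params@zoneAreaM2 / params@m2PerAcre
  c(revenuePerZone = round(params@revenuePerAcre * f, 1),
    fertilizerPerZone = round(params@fertilizerPerAcre * f, 1))
}

#' Labor cost of a scouting mission
#'
#' Autonomous policies need one unskilled worker for the duration of the
#' mission; exhaustive scouting additionally needs a skilled worker to
#' plan routes and swap batteries. Hours scale linearly with charges.
#'
#' @param policy Policy name ("exhaustive" engages both workers).
#' @param charges Number of battery charges used (>= 1).
#' @param params An \linkS4class{EconParams}.
#' @return Labor cost in USD.
#' @export
laborCost <- function(policy, charges, params = econParams()) {
  if (charges < 1) stop("charges must be at least 1")
  hours <- charges * params@hoursPerCharge
  rate <- params@wageUnskilled +
    if (policy == "exhaustive") params@wageSkilled else 0
  hours * rate
}

#' Labor-cost reduction factor between two missions
#'
#' @param costExhaustive,costAutonomous Labor costs in USD (the printed
#'   reference figures are $212 exhaustive and $44 autonomous at 40\%
#'   coverage).
#' @return Cost ratio, rounded to one decimal.
#' @examples
#' laborCostReduction(212, 44)  # 4.8
#' @export
laborCostReduction <- function(costExhaustive, costAutonomous) {
  round(costExhaustive / costAutonomous, 1)
}

#' Charges needed at a given coverage rate
#'
#' Charges scale linearly with zones visited: an exhaustive survey of one
#' hectare takes 29 charges, so 40\% coverage takes 12 (nearest integer).
#'
#' @param coverage Coverage fraction.
#' @param exhaustiveCharges Charges for full coverage of the area.
#' @return Integer charge count.
#' @export
chargesForCoverage <- function(coverage, exhaustiveCharges = 29) {
  as.integer(round(coverage * exhaustiveCharges))
}

#' Net revenue of a field under a predicted health map
#'
#' Full yield minus crop loss on missed unhealthy zones (classified
#' healthy, so untreated), minus treatment cost of every zone classified
#' unhealthy, minus labor: \code{n * 0.8 - 0.8 * fp - 0.1 * (tn + fn) -
#' labor} under the default per-zone constants.
#'
#' @param counts Confusion counts of the final map.
#' @param labor Labor cost in USD.
#' @param params An \linkS4class{EconParams}.
#' @return Net revenue in USD.
#' @export
netRevenue <- function(counts, labor = 0, params = econParams()) {
  pz <- perZoneConstants(params)
  n <- sum(counts)
  n * pz[["revenuePerZone"]] -
    pz[["revenuePerZone"]] * counts[["fp"]] -
    pz[["fertilizerPerZone"]] * (counts[["tn"]] + counts[["fn"]]) -
    labor
}

#' Nutrient-runoff risk of a treatment plan
#'
#' The percentage of truly healthy zones slated for unnecessary
#' fertilization (classified unhealthy): \code{100 * fn / (tp + fn)}.
#' Uniform blanket treatment (non-scouting) scores 100\%.
#'
#' @param counts Confusion counts of the final map.
#' @return Percentage in [0, 100]; NA when the field has no healthy zone.
#' @export
runoffRisk <- function(counts) {
  den <- counts[["tp"]] + counts[["fn"]]
  if (den == 0) return(NA_real_)
  100 * counts[["fn"]] / den
}
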