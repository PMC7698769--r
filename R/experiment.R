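## Desk-scale reproductions of the standard experimental sweeps: accuracy
## surfaces over coverage x window size, the healthy-vs-unhealthy field
## case study, and multi-policy economics comparisons.

.missionRow <- function(res, field, params) {
  cc <- confusionCounts(res@predictedMap, field@truth)
  met <- mapMetrics(cc)
  lab <- if (res@policy == "non_scouting") 0
         else laborCost(res@policy, res@charges, params)
  data.frame(policy = res@policy, coverage = res@coverage,
             steps = nrow(res@path), charges = res@charges,
             laborCost = lab, accuracy = met[["accuracy"]],
             posPrecision = met[["posPrecision"]],
             posRecall = met[["posRecall"]],
             negPrecision = met[["negPrecision"]],
             negRecall = met[["negRecall"]],
             netRevenue = netRevenue(cc, lab, params),
             runoffRisk = runoffRisk(cc),
             stringsAsFactors = FALSE)
}

#' Sweep scouting policies over coverage rates and window sizes
#'
#' Runs every (policy, coverage, window size, field) combination on freshly
#' generated synthetic fields and returns one tidy row per mission with all
#' map metrics and economics. Deterministic under \code{seed}: field i uses
#' spec seed \code{seed + i} and every mission derives its own seed from
#' the combination indices.
#'
#' @param spec Base \linkS4class{SyntheticFieldSpec} for the test fields.
#' @param policies Character vector of policy names for
#'   \code{\link{runMission}}.
#' @param coverages Numeric vector of coverage rates.
#' @param windowSizes Integer vector of window sizes (whole_field/random).
#' @param nFields Number of synthetic test fields.
#' @param ensemble,ref,dataset,localDataset Models passed through to
#'   \code{\link{runMission}}.
#' @param params An \linkS4class{EconParams}.
#' @param seed Base seed.
#' @return A data.frame with one row per mission.
#' @export
sweepScouting <- function(spec, policies = c("whole_field", "random"),
                          coverages = c(0.2, 0.4), windowSizes = 15L,
                          nFields = 5L, ensemble = NULL, ref = NULL,
                          dataset = NULL, localDataset = NULL,
                          params = econParams(), seed = 1L) {
  rows <- list()
  for (i in seq_len(nFields)) {
    fspec <- spec
    fspec@seed <- spec@seed + 500000L + as.integer(i)
    field <- generateField(fspec, tiles = !is.null(ensemble) &&
                             length(ensemble@featureNames) > 0L)
    for (ip in seq_along(policies)) {
      p <- policies[ip]
      fixed <- p %in% c("exhaustive", "non_scouting")
      combos <- if (fixed) cbind(1L, 1L)
                else as.matrix(expand.grid(seq_along(coverages),
                                           seq_along(windowSizes)))
      for (ci in seq_len(nrow(combos))) {
        ic <- combos[ci, 1L]; iw <- combos[ci, 2L]
        mseed <- seed + 7919L * i + 101L * ip + 13L * ic + iw
        res <- runMission(p, field, coverage = coverages[ic],
                          ensemble = ensemble, ref = ref, dataset = dataset,
                          localDataset = localDataset,
                          windowSize = windowSizes[iw], seed = mseed)
        row <- .missionRow(res, field, params)
        row$windowSize <- if (fixed) NA_integer_ else windowSizes[iw]
        row$field <- i
        row$seed <- mseed
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

#' Case study: largely healthy vs largely unhealthy fields
#'
#' Compares whole-field scouting accuracy on two field regimes (e.g., 5\%
#' vs 70\% unhealthy) at two coverage rates, exposing the
#' coverage-doubling accuracy gain for each regime.
#'
#' @param healthySpec,unhealthySpec \linkS4class{SyntheticFieldSpec}s for
#'   the two regimes.
#' @param coverages Two coverage rates (default 0.2 and 0.4).
#' @param nFields Fields per regime.
#' @param ensemble,ref,dataset Models for the whole_field policy.
#' @param seed Base seed.
#' @return A data.frame with columns \code{regime}, \code{coverage},
#'   \code{field}, \code{accuracy}.
#' @export
caseStudy <- function(healthySpec, unhealthySpec, coverages = c(0.2, 0.4),
                      nFields = 3L, ensemble, ref, dataset, seed = 1L) {
  specs <- list(healthy = healthySpec, unhealthy = unhealthySpec)
  rows <- list()
  for (rg in names(specs)) for (i in seq_len(nFields)) {
    fspec <- specs[[rg]]
    fspec@seed <- fspec@seed + 600000L + as.integer(i)
    field <- generateField(fspec)
    for (ic in seq_along(coverages)) {
      res <- runMission("whole_field", field, coverage = coverages[ic],
                        ensemble = ensemble, ref = ref, dataset = dataset,
                        windowSize = dataset@windowSize,
                        seed = seed + 31L * i + ic)
      cc <- confusionCounts(res@predictedMap, field@truth)
      rows[[length(rows) + 1L]] <- data.frame(
        regime = rg, coverage = coverages[ic], field = i,
        accuracy = mapMetrics(cc)[["accuracy"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
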