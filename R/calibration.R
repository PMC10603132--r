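#' @include pcmci.R
#' @include simulate.R
NULL

#' False-positive calibration of the MCI stage under the global null
#'
#' Runs the full two-stage procedure on panels of mutually independent
#' Gaussian white-noise series and pools every MCI-stage p-value. Under the
#' global null the fraction of p-values at or below the significance level
#' estimates the procedure's false-positive rate, which should match the
#' nominal level.
#'
#' @param seeds integer vector; one independent panel is generated per
#'   seed.
#' @param nVars,nWeeks panel dimensions (defaults 5 and 500).
#' @param config a [PCMCIConfig-class] (default `tauMax = 5` at the
#'   standard 0.05 level).
#' @param keepP logical; return the pooled p-values as well.
#' @return List: `fraction` (of pooled MCI p-values at or below
#'   `config@alpha`), `nTests` (pooled test count), `nPanels`, `alpha`,
#'   and, when `keepP`, `pvalues`.
#' @examples
#' nullCalibration(seeds = 1:5)$fraction
#' @export
nullCalibration <- function(seeds = 1:500, nVars = 5, nWeeks = 500,
                            config = pcmciConfig(tauMax = 5),
                            keepP = FALSE) {
  pool <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    p <- generateNullPanel(nVars, nWeeks, seed = seeds[i])
    vars <- colnames(panelValues(p))
    parents <- lapply(vars, function(v)
      pcConditionSelection(p, v, config))
    names(parents) <- vars
    mci <- mciTestAll(p, parents, config)
    pool[[i]] <- mci$p[!is.na(mci$p)]
  }
  pv <- unlist(pool)
  out <- list(fraction = mean(pv <= config@alpha),
              nTests = length(pv), nPanels = length(seeds),
              alpha = config@alpha)
  if (keepP) out$pvalues <- pv
  out
}
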