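#' @include pcor.R
NULL

#' PC condition selection for one target variable
#'
#' The first stage of the two-stage discovery: a Markov-set search that
#' prunes, per target, the lagged candidates that fail an iterative
#' conditional-independence test. Candidates are all `(variable, lag)`
#' pairs with lag in `[max(tauMin, 1), tauMax]`. At conditioning dimension
#' `q = 0` every candidate is tested unconditionally; for growing
#' `q = 1..qMax` each surviving candidate is tested against the target
#' conditioned on the `q` currently strongest *other* survivors (ranked by
#' the minimum `|rho|` seen so far), and candidates with `p > pcAlpha` are
#' removed after each full pass (stable removal). Survivors are returned
#' sorted by decreasing minimum `|rho|`.
#'
#' All selection-stage tests share the sample `t = tauMax + 1 .. T` so
#' candidate strengths are comparable.
#'
#' @param panel a [FirePanel-class] of preprocessed anomalies.
#' @param target variable identifier.
#' @param config a [PCMCIConfig-class].
#' @return data.frame of parents: `var`, `lag`, `absmin` (minimum `|rho|`
#'   across the candidate's tests), `pvalue` (of the last test), sorted by
#'   decreasing `absmin`. Possibly zero rows.
#' @seealso [runPCMCI()]
#' @export
pcConditionSelection <- function(panel, target, config = pcmciConfig()) {
  V <- panelValues(panel)
  Tn <- nrow(V)
  yvar <- match(target, colnames(V))
  if (is.na(yvar)) stop(sprintf("unknown target '%s'", target))
  hasNA <- anyNA(V)
  lo <- max(config@tauMin, 1L)
  empty <- data.frame(var = integer(0), lag = integer(0),
                      absmin = numeric(0), pvalue = numeric(0))
  if (config@tauMax < lo) return(empty)  # no lagged candidates exist
  lags <- lo:config@tauMax
  cand <- data.frame(var = rep(seq_len(ncol(V)), times = length(lags)),
                     lag = rep(lags, each = ncol(V)))

  rows <- (config@tauMax + 1L):Tn
  y <- V[rows, yvar]
  Cm <- vapply(seq_len(nrow(cand)),
               function(k) V[rows - cand$lag[k], cand$var[k]],
               numeric(length(rows)))
  r <- suppressWarnings(
    as.vector(cor(y, Cm, use = "pairwise.complete.obs")))
  r[is.na(r)] <- 0
  nEff <- if (hasNA) colSums(!is.na(Cm) & !is.na(y)) else
    rep(length(y), ncol(Cm))
  df <- pmax(nEff - 2, 1)
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df)

  keep <- p <= config@pcAlpha
  surv <- cand[keep, , drop = FALSE]
  surv$absmin <- abs(r[keep])
  surv$pvalue <- p[keep]

  q <- 1L
  while (q <= config@qMax && nrow(surv) - 1L >= q) {
    ord <- order(-surv$absmin)
    surv <- surv[ord, , drop = FALSE]
    removed <- rep(FALSE, nrow(surv))
    for (i in seq_len(nrow(surv))) {
      others <- setdiff(seq_len(nrow(surv)), i)
      Zc <- surv[others[seq_len(q)], c("var", "lag"), drop = FALSE]
      res <- .pcorIdx(V, surv$var[i], surv$lag[i], yvar, Zc, hasNA, Tn)
      if (is.na(res[2]) || res[2] > config@pcAlpha) {
        removed[i] <- TRUE
      } else {
        surv$absmin[i] <- min(surv$absmin[i], abs(res[1]))
        surv$pvalue[i] <- res[2]
      }
    }
    surv <- surv[!removed, , drop = FALSE]
    q <- q + 1L
  }
  surv <- surv[order(-surv$absmin, surv$lag, surv$var), , drop = FALSE]
  rownames(surv) <- NULL
  surv
}

#' Momentary conditional independence tests over all lagged pairs
#'
#' The second stage: for every ordered pair `(X, Y)` and lag `tau` in
#' `[tauMin, tauMax]` (`tau >= 1` when `X = Y`), tests
#' `X_{t-tau} independent of Y_t` given the union of `parents(Y)` minus the
#' tested pair and the lag-shifted `parents(X)`; each side contributes at
#' most `maxConds` (strongest-first) conditioners. Conditioning on both
#' parent sets is what controls the false-positive rate in the presence of
#' autocorrelation. Each test is aligned on `t = maxlag + 1 .. T` for its
#' own maximal lag (so the effective sample is as large as the lags allow),
#' with listwise deletion over missing entries.
#'
#' @param panel a [FirePanel-class].
#' @param parents named list of selection-stage parent data.frames (one per
#'   variable, as returned by [pcConditionSelection()]).
#' @param config a [PCMCIConfig-class].
#' @return List of arrays `rho`, `p`, `ess`, each `source x target x lag`
#'   with dimnames; entries that are never tested (`X = Y` at lag 0) or
#'   with insufficient effective sample are `NA`.
#' @export
mciTestAll <- function(panel, parents, config = pcmciConfig()) {
  V <- panelValues(panel)
  Tn <- nrow(V)
  nv <- ncol(V)
  vars <- colnames(V)
  hasNA <- anyNA(V)
  taus <- config@tauMin:config@tauMax
  dn <- list(vars, vars, as.character(taus))
  rho <- array(NA_real_, c(nv, nv, length(taus)), dimnames = dn)
  p <- array(NA_real_, c(nv, nv, length(taus)), dimnames = dn)
  ess <- array(NA_real_, c(nv, nv, length(taus)), dimnames = dn)

  paIdx <- lapply(vars, function(v) {
    pa <- parents[[v]]
    if (is.null(pa) || !nrow(pa))
      data.frame(var = integer(0), lag = integer(0))
    else data.frame(var = pa$var, lag = pa$lag)
  })

  for (src in seq_len(nv)) {
    paS <- paIdx[[src]]
    for (tgt in seq_len(nv)) {
      paT <- paIdx[[tgt]]
      for (ti in seq_along(taus)) {
        tau <- taus[ti]
        if (src == tgt && tau == 0L) next
        zy <- paT[!(paT$var == src & paT$lag == tau), , drop = FALSE]
        zy <- head(zy, config@maxConds)
        zx <- head(paS, config@maxConds)
        if (nrow(zx)) zx$lag <- zx$lag + tau
        Z <- rbind(zy, zx)
        if (nrow(Z))
          Z <- Z[!duplicated(paste(Z$var, Z$lag)), , drop = FALSE]
        res <- .pcorIdx(V, src, tau, tgt, Z, hasNA, Tn)
        rho[src, tgt, ti] <- res[1]
        p[src, tgt, ti] <- res[2]
        ess[src, tgt, ti] <- res[3]
      }
    }
  }
  list(rho = rho, p = p, ess = ess)
}

#' Two-stage lagged causal discovery on a panel
#'
#' Composes [pcConditionSelection()] (per variable) and [mciTestAll()],
#' then retains the links whose MCI p-value is at or below `alpha`.
#' Contemporaneous (lag-0) links between two non-target variables are
#' discarded; a significant lag-0 association between a precursor and the
#' target is oriented precursor -> target a priori (same-week weather and
#' fuel states may affect burning; reverse same-week causation is excluded
#' by construction). The full rho/p/effective-sample audit arrays are kept
#' on the returned graph. The procedure is fully deterministic given the
#' panel.
#'
#' @param panel a [FirePanel-class] of detrended, deseasonalized anomalies
#'   (`nWeeks > tauMax + 50` required).
#' @param config a [PCMCIConfig-class].
#' @return A [CausalGraph-class]; an empty link set is a valid result.
#' @examples
#' sc <- scenarioSpec(c("X", "BA"), c("top-down", "target"),
#'                    links = plantedLink("X", "BA", 2, 0.6),
#'                    nWeeks = 400, seed = 11)
#' g <- runPCMCI(simulatePanel(sc), pcmciConfig(tauMax = 5))
#' causalLinks(g)
#' @export
runPCMCI <- function(panel, config = pcmciConfig()) {
  validObject(config)
  V <- panelValues(panel)
  if (nrow(V) <= config@tauMax + 50L)
    stop("panel too short: need nWeeks > tauMax + 50")
  vars <- colnames(V)
  groups <- unname(variableGroups(panel))
  tgt <- targetVariable(panel)

  parents <- lapply(vars, function(v)
    pcConditionSelection(panel, v, config))
  names(parents) <- vars

  mci <- mciTestAll(panel, parents, config)
  taus <- config@tauMin:config@tauMax

  pAdj <- mci$p
  if (config@bh) {
    flat <- as.vector(pAdj)
    tested <- !is.na(flat)
    flat[tested] <- stats::p.adjust(flat[tested], method = "BH")
    pAdj <- array(flat, dim(mci$p), dimnames = dimnames(mci$p))
  }

  links <- NULL
  hit <- which(!is.na(pAdj) & pAdj <= config@alpha, arr.ind = TRUE)
  if (nrow(hit)) {
    links <- data.frame(source = vars[hit[, 1]], target = vars[hit[, 2]],
                        lag = taus[hit[, 3]],
                        rho = mci$rho[hit],
                        pvalue = mci$p[hit],
                        stringsAsFactors = FALSE)
    lag0 <- links$lag == 0L
    srcIsTgt <- links$source == tgt
    tgtIsTgt <- links$target == tgt
    # lag-0: keep only precursor -> target orientation
    drop <- lag0 & !(tgtIsTgt & !srcIsTgt)
    links <- links[!drop, , drop = FALSE]
    links <- links[order(-abs(links$rho), links$lag, links$source), ,
                   drop = FALSE]
    rownames(links) <- NULL
  } else {
    links <- data.frame(source = character(0), target = character(0),
                        lag = integer(0), rho = numeric(0),
                        pvalue = numeric(0), stringsAsFactors = FALSE)
  }

  new("CausalGraph", links = links, parents = parents, config = config,
      rho = mci$rho, p = mci$p, ess = mci$ess,
      variables = vars, groups = groups)
}
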