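#' Taguchi signal-to-noise ratio
#'
#' The three classical S/N criteria, in dB:
#' \itemize{
#'   \item larger-is-better: \eqn{-10 log10( (1/n) \sum 1/y_i^2 )}
#'   \item smaller-is-better: \eqn{-10 log10( (1/n) \sum y_i^2 )}
#'   \item nominal-is-best: \eqn{10 log10( \bar{y}^2 / s^2 )}
#' }
#' With a single observation the larger-is-better ratio reduces to
#' \eqn{20 log10(y)}, the regime of the packaged study where only
#' per-treatment means are available.
#'
#' @param values numeric vector of observations for one run (n >= 1;
#'   n >= 2 for \code{"nominal"}).
#' @param criterion one of \code{"larger"}, \code{"smaller"},
#'   \code{"nominal"}.
#' @return S/N in dB (single number).
#' @examples
#' snRatio(10)            # 20 dB
#' snRatio(52.50)         # 34.40 dB
#' @export
snRatio <- function(values, criterion = c("larger", "smaller", "nominal")) {
  criterion <- match.arg(criterion)
  if (length(values) == 0L || anyNA(values))
    stop("'values' must be non-empty and free of NA")
  switch(criterion,
    larger = {
      if (any(values <= 0))
        stop("larger-is-better S/N requires strictly positive values")
      -10 * log10(mean(1 / values^2))
    },
    smaller = -10 * log10(mean(values^2)),
    nominal = {
      if (length(values) < 2L)
        stop("nominal-is-best S/N needs at least 2 values")
      s2 <- var(values)
      if (s2 == 0)
        stop("zero variance: nominal-is-best S/N is infinite")
      10 * log10(mean(values)^2 / s2)
    })
}

#' Per-run S/N values of a designed experiment
#'
#' Applies \code{\link{snRatio}} to each (parameter, run) cell. With the
#' packaged per-treatment means there is one observation per cell, so the
#' larger-is-better S/N is \eqn{20 log10(y)}.
#'
#' @param x a \code{\link{TaguchiExperiment}}.
#' @param criterion S/N criterion; the study maximizes every response, so
#'   the default is \code{"larger"}.
#' @return numeric matrix of dB values, parameters x runs.
#' @aliases snValues,TaguchiExperiment-method
#' @export
setMethod("snValues", "TaguchiExperiment",
  function(x, criterion = c("larger", "smaller", "nominal")) {
    criterion <- match.arg(criterion)
    m <- responses(x)
    # one observation per cell: closed forms of snRatio at n = 1
    out <- switch(criterion,
      larger = {
        if (any(m <= 0))
          stop("larger-is-better S/N requires strictly positive values")
        20 * log10(m)
      },
      smaller = -20 * log10(abs(m)),
      nominal = stop("nominal-is-best S/N needs replicate values; ",
                     "this experiment stores one value per run"))
    dimnames(out) <- dimnames(m)
    out
  })

#' MainEffectsTable: level means, delta and rank of each factor
#'
#' Produced by \code{\link{mainEffects}}. Holds, per factor, the mean S/N at
#' each of the three levels (each the average of 9 runs on a balanced L27),
#' the delta (max - min of the level means), the delta rank (1 = most
#' influential), and tie flags. The raw-response level means are carried for
#' diagnostics but never ranked.
#'
#' @slot parameter measured parameter name.
#' @slot species species tag.
#' @slot criterion S/N criterion used.
#' @slot grandMean grand mean S/N (dB).
#' @slot table data.frame: factor, level1, level2, level3 (dB), delta, rank,
#'   best_level, tie.
#' @slot rawTable data.frame of raw-response level means (diagnostic).
#' @aliases MainEffectsTable show,MainEffectsTable-method
#' @exportClass MainEffectsTable
setClass("MainEffectsTable",
  representation(parameter = "character", species = "character",
                 criterion = "character", grandMean = "numeric",
                 table = "data.frame", rawTable = "data.frame"))

setValidity("MainEffectsTable", function(object) {
  tb <- object@table
  msg <- character(0)
  if (!all(c("factor", "level1", "level2", "level3", "delta", "rank",
             "best_level", "tie") %in% names(tb)))
    msg <- c(msg, "table is missing required columns")
  else {
    if (any(tb$delta < 0)) msg <- c(msg, "delta must be >= 0")
    if (!identical(sort(tb$rank), seq_len(nrow(tb))))
      msg <- c(msg, "ranks must be a permutation of 1..k")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MainEffectsTable", function(object) {
  cat(sprintf("MainEffectsTable: %s / %s (%s-is-better S/N)\n",
              object@species, object@parameter, object@criterion))
  cat(sprintf("  grand mean: %.3f dB\n", object@grandMean))
  tb <- object@table
  tb[2:5] <- lapply(tb[2:5], round, 3)
  print(tb, row.names = FALSE)
})

#' Main-effects analysis of a designed experiment
#'
#' For one measured parameter, averages the per-run S/N within each coded
#' level of each factor (9 runs per level on the L27), computes the delta
#' (range of the three level means) and ranks the factors by descending
#' delta. Delta ties are broken by design-matrix factor order (earlier
#' factor gets the better rank) and flagged in the \code{tie} column.
#'
#' @param x a \code{\link{TaguchiExperiment}}.
#' @param parameter row name of the response to analyse.
#' @param criterion S/N criterion (default larger-is-better).
#' @return a \code{\linkS4class{MainEffectsTable}}.
#' @examples
#' me <- mainEffects(loadStudy("lettuce"), "fresh_leaf")
#' bestLevels(me)["ec"]  # level 2 (EC 0.9 dS/m)
#' @aliases mainEffects,TaguchiExperiment-method
#' @export
setMethod("mainEffects", "TaguchiExperiment",
  function(x, parameter, criterion = "larger") {
    if (!parameter %in% rownames(x))
      stop("unknown parameter '", parameter, "'")
    dm <- designMatrix(x)
    rep <- orthogonalityReport(dm)
    if (!rep$pass)
      stop("design is not a balanced strength-2 array; offending columns: ",
           paste(unique(c(rep$badColumns, rep$badPairs)), collapse = ", "))
    sn <- snValues(x, criterion = criterion)[parameter, ]
    y <- responses(x)[parameter, ]
    lev <- function(v) t(vapply(colnames(dm), function(f)
      tapply(v, factor(dm[, f], 1:3), mean), numeric(3)))
    lm <- lev(sn)
    delta <- apply(lm, 1, max) - apply(lm, 1, min)
    ord <- order(-delta, seq_along(delta))  # ties -> earlier factor first
    rank <- integer(length(delta)); rank[ord] <- seq_along(delta)
    tie <- duplicated(delta) | duplicated(delta, fromLast = TRUE)
    tb <- data.frame(factor = colnames(dm),
                     level1 = lm[, 1], level2 = lm[, 2], level3 = lm[, 3],
                     delta = delta, rank = rank,
                     best_level = apply(lm, 1, which.max), tie = tie,
                     row.names = NULL, stringsAsFactors = FALSE)
    rlm <- lev(y)
    raw <- data.frame(factor = colnames(dm), level1 = rlm[, 1],
                      level2 = rlm[, 2], level3 = rlm[, 3],
                      row.names = NULL, stringsAsFactors = FALSE)
    new("MainEffectsTable", parameter = parameter,
        species = studySpecies(x), criterion = criterion,
        grandMean = mean(sn), table = tb, rawTable = raw)
  })

#' Optimal coded level per factor
#'
#' The level with maximal mean S/N for each factor. Exact ties are broken
#' toward the lowest level index and flagged in the \code{"tie"} attribute.
#'
#' @param x a \code{\linkS4class{MainEffectsTable}} or
#'   \code{\link{TaguchiExperiment}} (the latter requires \code{parameter}).
#' @param ... passed to \code{\link{mainEffects}} for the experiment method.
#' @return named integer vector of coded levels with logical attribute
#'   \code{"tie"}.
#' @aliases bestLevels,MainEffectsTable-method bestLevels,TaguchiExperiment-method
#' @export
setMethod("bestLevels", "MainEffectsTable", function(x, ...) {
  tb <- x@table
  lm <- as.matrix(tb[, c("level1", "level2", "level3")])
  best <- apply(lm, 1, which.max)  # which.max -> lowest index on ties
  tie <- apply(lm, 1, function(v) sum(v == max(v)) > 1L)
  structure(setNames(as.integer(best), tb$factor), tie = setNames(tie, tb$factor))
})

setMethod("bestLevels", "TaguchiExperiment", function(x, parameter, ...) {
  bestLevels(mainEffects(x, parameter, ...))
})
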