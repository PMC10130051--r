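#' Cell means of a factor pair
#'
#' Mean per-run S/N in each of the 9 level combinations of two factors. On
#' a strength-2 L27 every cell averages exactly 3 runs, so the matrix is
#' always fully populated.
#'
#' @param x a \code{\link{TaguchiExperiment}}.
#' @param parameter response row.
#' @param factorA,factorB distinct factor names.
#' @param criterion S/N criterion.
#' @return 3x3 numeric matrix; rows are \code{factorA} levels, columns
#'   \code{factorB} levels.
#' @export
interactionCellMeans <- function(x, parameter, factorA, factorB,
                                 criterion = "larger") {
  if (identical(factorA, factorB))
    stop("'factorA' and 'factorB' must differ")
  dm <- designMatrix(x)
  if (!all(c(factorA, factorB) %in% colnames(dm)))
    stop("unknown factor name")
  sn <- snValues(x, criterion = criterion)[parameter, ]
  m <- tapply(sn, list(factor(dm[, factorA], 1:3), factor(dm[, factorB], 1:3)),
              mean)
  dimnames(m) <- list(paste0(factorA, 1:3), paste0(factorB, 1:3))
  m
}

#' Non-parallelism score of a cell-mean matrix
#'
#' Interaction plots show one line per level of the second factor; parallel
#' lines mean the cell means are additive in row and column effects. The
#' score is the largest absolute non-additive residual after double
#' centering: \eqn{max_{ij} | m_{ij} - (r_i + c_j - g) |} with row means
#' \eqn{r}, column means \eqn{c} and grand mean \eqn{g}. It is 0 exactly
#' when the lines are parallel, invariant to adding a constant and to
#' transposing the matrix.
#'
#' @param cells 3x3 (or any) numeric matrix of cell means in dB.
#' @return non-negative score in dB.
#' @export
nonparallelism <- function(cells) {
  if (any(!is.finite(cells))) stop("cell means must be finite")
  resid <- cells - outer(rowMeans(cells), colMeans(cells), "+") + mean(cells)
  max(abs(resid))
}

#' Screen all factor pairs for two-factor interactions
#'
#' Computes the non-parallelism score of every factor pair (15 pairs for 6
#' factors) and flags pairs whose score exceeds a threshold. The default
#' threshold for a pair is 10% of the larger of the two factors' deltas
#' from the main-effects analysis, a scale-aware operationalization of the
#' "almost parallel lines" judgement used in interaction plots.
#'
#' @param x a \code{\link{TaguchiExperiment}}.
#' @param parameter response row.
#' @param threshold fixed dB threshold for all pairs, or \code{NULL}
#'   (default) for the per-pair 10%-of-delta rule.
#' @param thresholdFrac fraction of the larger delta used when
#'   \code{threshold} is \code{NULL}.
#' @param criterion S/N criterion.
#' @return data.frame sorted by descending score: \code{factor_a, factor_b,
#'   score_db, threshold_db, interacting}.
#' @aliases interactionSummary,TaguchiExperiment-method
#' @export
setMethod("interactionSummary", "TaguchiExperiment",
  function(x, parameter, threshold = NULL, thresholdFrac = 0.1,
           criterion = "larger") {
    if (!is.null(threshold) && threshold < 0)
      stop("'threshold' must be >= 0")
    dm <- designMatrix(x)
    me <- mainEffects(x, parameter, criterion = criterion)
    delta <- setNames(me@table$delta, me@table$factor)
    pairs <- combn(colnames(dm), 2L, simplify = FALSE)
    out <- do.call(rbind, lapply(pairs, function(p) {
      sc <- nonparallelism(
        interactionCellMeans(x, parameter, p[1], p[2], criterion = criterion))
      th <- if (is.null(threshold)) thresholdFrac * max(delta[p]) else threshold
      data.frame(factor_a = p[1], factor_b = p[2], score_db = sc,
                 threshold_db = th, interacting = sc > th,
                 stringsAsFactors = FALSE)
    }))
    out <- out[order(-out$score_db), ]
    rownames(out) <- NULL
    out
  })
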