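## L27(3^13) construction over GF(3).
##
## Every run index i in 0..26 has a base-3 expansion (a, b, c). Each of the
## 13 columns of the full L27 array is a nonzero linear combination
## ca*a + cb*b + cc*c (mod 3), one representative per projective line, so any
## two distinct columns are linearly independent and the array has strength 2.
## The first six combinations are ordered so that the 6-factor array equals
## the published vertical-farm trial matrix column-for-column.
.L27_COEF <- matrix(c(
  1L, 0L, 0L,   # co2
  0L, 1L, 0L,   # led
  1L, 1L, 0L,   # ec
  2L, 1L, 0L,   # day_temp
  0L, 0L, 1L,   # night_temp
  1L, 0L, 1L,   # humidity
  1L, 0L, 2L,
  0L, 1L, 1L,
  0L, 1L, 2L,
  1L, 1L, 1L,
  1L, 1L, 2L,
  1L, 2L, 1L,
  1L, 2L, 2L), ncol = 3L, byrow = TRUE)

.CEA_FACTORS <- c("co2", "led", "ec", "day_temp", "night_temp", "humidity")

#' Construct the L27 three-level orthogonal array
#'
#' Builds the 27-run, strength-2 orthogonal array with up to 13 three-level
#' columns coded \code{1:3}. For \code{nFactors = 6} the column assignment
#' reproduces the vertical-farm trial matrix used by the packaged study
#' (CO2, LED recipe, EC, day temperature, night temperature, relative
#' humidity) row-for-row. The construction is deterministic: runs are the
#' 27 points of the base-3 expansion of \code{0:26} and columns are fixed
#' linear combinations of its three digits over GF(3).
#'
#' @param nFactors integer, number of three-level columns (1 to 13).
#' @param factorNames optional character vector of column names; defaults to
#'   the six study factor names followed by \code{F7, F8, ...}.
#' @return integer matrix with 27 rows (named \code{run1..run27}) and
#'   \code{nFactors} columns, cells in \code{1:3}.
#' @examples
#' dm <- l27Design()
#' dm["run10", ]  # 2 1 2 3 1 2
#' @export
l27Design <- function(nFactors = 6L, factorNames = NULL) {
  nFactors <- as.integer(nFactors)
  if (length(nFactors) != 1L || is.na(nFactors) || nFactors < 1L)
    stop("'nFactors' must be a single integer >= 1")
  if (nFactors > 13L)
    stop("L27 supports at most 13 three-level columns; got ", nFactors)
  i <- 0:26
  digits <- cbind(i %/% 9L, (i %/% 3L) %% 3L, i %% 3L)
  coef <- .L27_COEF[seq_len(nFactors), , drop = FALSE]
  dm <- (digits %*% t(coef)) %% 3L + 1L
  storage.mode(dm) <- "integer"
  if (is.null(factorNames)) {
    factorNames <- c(.CEA_FACTORS, paste0("F", 7:13))[seq_len(nFactors)]
  } else if (length(factorNames) != nFactors) {
    stop("'factorNames' must have length ", nFactors)
  }
  dimnames(dm) <- list(paste0("run", 1:27), factorNames)
  dm
}

#' Check level balance and strength-2 orthogonality of a coded design
#'
#' Counts level occurrences per column and ordered level-pair occurrences per
#' column pair. A three-level orthogonal array on 27 runs must show each
#' level 9 times in every column and each of the 9 ordered pairs 3 times in
#' every column pair.
#'
#' @param dm integer matrix of coded levels in \code{1:3}.
#' @return a list with elements \code{levelCounts} (3 x k matrix),
#'   \code{pairCounts} (data.frame of per-pair counts), \code{badColumns},
#'   \code{badPairs} and logical \code{pass}.
#' @export
orthogonalityReport <- function(dm) {
  if (is.null(dim(dm)) || nrow(dm) == 0L || ncol(dm) == 0L)
    stop("design matrix is empty")
  bad <- which(!(dm %in% 1:3 & dm == round(dm)), arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("invalid coded level at run %s, factor '%s' (value %s)",
                 bad[1, 1], colnames(dm)[bad[1, 2]], dm[bad[1, 1], bad[1, 2]]))
  }
  k <- ncol(dm)
  fac <- colnames(dm)
  if (is.null(fac)) fac <- paste0("F", seq_len(k))
  levelCounts <- vapply(seq_len(k),
                        function(j) tabulate(dm[, j], nbins = 3L), integer(3))
  dimnames(levelCounts) <- list(paste0("level", 1:3), fac)
  perLevel <- nrow(dm) / 3
  badColumns <- fac[apply(levelCounts, 2, function(ct) any(ct != perLevel))]

  pairs <- if (k >= 2L) combn(k, 2L, simplify = FALSE) else list()
  perPair <- nrow(dm) / 9
  pairCounts <- do.call(rbind, lapply(pairs, function(p) {
    tb <- table(factor(dm[, p[1]], 1:3), factor(dm[, p[2]], 1:3))
    data.frame(factor_a = fac[p[1]], factor_b = fac[p[2]],
               level_a = rep(1:3, 3), level_b = rep(1:3, each = 3),
               count = as.vector(tb))
  }))
  badPairs <- character(0)
  if (!is.null(pairCounts)) {
    off <- pairCounts[pairCounts$count != perPair, , drop = FALSE]
    badPairs <- unique(paste(off$factor_a, off$factor_b, sep = ":"))
  }
  list(levelCounts = levelCounts, pairCounts = pairCounts,
       badColumns = badColumns, badPairs = badPairs,
       pass = length(badColumns) == 0L && length(badPairs) == 0L)
}

#' Factor catalog for the packaged vertical-farm study
#'
#' The six environmental factors and their three physical levels: CO2
#' concentration (400/600/800 ppm), LED recipe (white at 122 PPFD, white +
#' deep-red + far-red at 122 PPFD, white + deep-red + far-red at 244 PPFD),
#' nutrient-solution EC (0.7/0.9/1.2 dS/m), day temperature (15/22/26 C),
#' night temperature (10/15/20 C) and relative humidity (35/55/75 %).
#'
#' For the LED factor the \code{value} column carries the PPFD component of
#' the recipe (122, 122, 244) and \code{label} the recipe name; for all other
#' factors \code{value} is the physical setting and \code{label} its printed
#' form.
#'
#' @return data.frame with columns \code{factor}, \code{level}, \code{label},
#'   \code{value}, \code{units}; 18 rows (6 factors x 3 levels).
#' @export
ceaFactorCatalog <- function() {
  data.frame(
    factor = rep(.CEA_FACTORS, each = 3L),
    level = rep(1:3, times = 6L),
    label = c("400", "600", "800",
              "W122", "WRF122", "WRF244",
              "0.7", "0.9", "1.2",
              "15", "22", "26",
              "10", "15", "20",
              "35", "55", "75"),
    value = c(400, 600, 800,
              122, 122, 244,
              0.7, 0.9, 1.2,
              15, 22, 26,
              10, 15, 20,
              35, 55, 75),
    units = rep(c("ppm", "PPFD", "dS m^-1", "degC", "degC", "%"), each = 3L),
    stringsAsFactors = FALSE)
}

#' Decode a coded design to physical settings
#'
#' Replaces each coded level with the corresponding physical label from a
#' factor catalog. The decoding is invertible via \code{encodeDesign}.
#'
#' @param dm coded integer design matrix (columns named after catalog factors).
#' @param catalog factor catalog data.frame as from \code{ceaFactorCatalog}.
#' @return data.frame of physical labels, same dimensions and dimnames as
#'   \code{dm}.
#' @examples
#' decodeDesign(l27Design())["run1", ]  # 400, W122, 0.7, 15, 10, 35
#' @export
decodeDesign <- function(dm, catalog = ceaFactorCatalog()) {
  miss <- setdiff(colnames(dm), unique(catalog$factor))
  if (length(miss))
    stop("factors absent from catalog: ", paste(miss, collapse = ", "))
  out <- as.data.frame(lapply(colnames(dm), function(f) {
    levs <- catalog[catalog$factor == f, ]
    levs$label[match(dm[, f], levs$level)]
  }), col.names = colnames(dm), stringsAsFactors = FALSE)
  rownames(out) <- rownames(dm)
  out
}

#' @rdname decodeDesign
#' @param decoded data.frame of physical labels as produced by
#'   \code{decodeDesign}.
#' @export
encodeDesign <- function(decoded, catalog = ceaFactorCatalog()) {
  miss <- setdiff(colnames(decoded), unique(catalog$factor))
  if (length(miss))
    stop("factors absent from catalog: ", paste(miss, collapse = ", "))
  out <- vapply(colnames(decoded), function(f) {
    levs <- catalog[catalog$factor == f, ]
    code <- levs$level[match(as.character(decoded[[f]]), levs$label)]
    if (anyNA(code))
      stop("unknown label for factor '", f, "'")
    code
  }, integer(nrow(decoded)))
  rownames(out) <- rownames(decoded)
  out
}

#' Physical value of a coded level
#'
#' @param factor factor name present in the catalog.
#' @param level coded level in \code{1:3}.
#' @param catalog factor catalog.
#' @return numeric physical value (for the LED factor, the PPFD component).
#' @export
levelValue <- function(factor, level, catalog = ceaFactorCatalog()) {
  row <- catalog[catalog$factor == factor & catalog$level == level, ]
  if (nrow(row) != 1L)
    stop("no catalog entry for factor '", factor, "' level ", level)
  row$value
}
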