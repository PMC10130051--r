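#' Chlorophyll concentration from acetone-extract absorbances
#'
#' Implements the study's printed chlorophyll equations verbatim for a
#' fresh-leaf sample extracted in 80% acetone and read at 663.2 and
#' 646.8 nm:
#' \deqn{Chl_a = (12.25 A_{663.2} - A_{646.8}) \cdot V / (1000 W)}
#' \deqn{Chl_b = (25.51 A_{646.8} - A_{663.2}) \cdot V / (1000 W)}
#' with extract volume V (mL) and fresh mass W (g). The printed
#' \code{x V/1000 x W} is read as per-mass normalization
#' \code{x V/(1000 W)}, the only dimensionally sensible form for a
#' per-gram concentration. Note these printed coefficients differ from the
#' commonly cited spectrophotometric equations; they are implemented as
#' published rather than silently corrected.
#'
#' Negative concentrations (possible when one absorbance dominates) are
#' returned as-is with a \code{"flagged"} attribute rather than clamped.
#'
#' @param a663_2 absorbance at 663.2 nm (>= 0).
#' @param a646_8 absorbance at 646.8 nm (>= 0).
#' @param volume_ml extract volume in mL (> 0).
#' @param mass_g fresh sample mass in g (> 0).
#' @return concentration in mg per g fresh weight, vectorized; attribute
#'   \code{"flagged"} marks negative results.
#' @examples
#' chlA(0.5, 0.2, volume_ml = 5, mass_g = 0.1)  # 0.29625
#' @export
chlA <- function(a663_2, a646_8, volume_ml = 5, mass_g = 0.1) {
  .chl_check(a663_2, a646_8, volume_ml, mass_g)
  .flag((12.25 * a663_2 - a646_8) * volume_ml / (1000 * mass_g))
}

#' @rdname chlA
#' @export
chlB <- function(a663_2, a646_8, volume_ml = 5, mass_g = 0.1) {
  .chl_check(a663_2, a646_8, volume_ml, mass_g)
  .flag((25.51 * a646_8 - a663_2) * volume_ml / (1000 * mass_g))
}

#' @rdname chlA
#' @param mode \code{"as_printed"} computes chlb - chla (the study's literal
#'   total-chlorophyll formula, almost certainly a typographical variant of
#'   a sum); \code{"sum"} computes the conventional chla + chlb. The mode is
#'   recorded as an attribute of the result.
#' @export
chlTotal <- function(a663_2, a646_8, volume_ml = 5, mass_g = 0.1,
                     mode = c("as_printed", "sum")) {
  mode <- match.arg(mode)
  a <- chlA(a663_2, a646_8, volume_ml, mass_g)
  b <- chlB(a663_2, a646_8, volume_ml, mass_g)
  out <- if (mode == "as_printed") as.numeric(b) - as.numeric(a)
         else as.numeric(a) + as.numeric(b)
  structure(.flag(out), mode = mode)
}

#' @rdname chlA
#' @param df data.frame with columns
#'   \code{sample_id, a663_2, a646_8, volume_ml, mass_g}.
#' @return for \code{chlorophyllTable}: the input with added columns
#'   \code{chl_a, chl_b, chl_total, flagged}.
#' @export
chlorophyllTable <- function(df, mode = c("as_printed", "sum")) {
  mode <- match.arg(mode)
  need <- c("sample_id", "a663_2", "a646_8", "volume_ml", "mass_g")
  if (!all(need %in% names(df)))
    stop("need columns ", paste(need, collapse = ", "))
  df$chl_a <- as.numeric(chlA(df$a663_2, df$a646_8, df$volume_ml, df$mass_g))
  df$chl_b <- as.numeric(chlB(df$a663_2, df$a646_8, df$volume_ml, df$mass_g))
  df$chl_total <- as.numeric(chlTotal(df$a663_2, df$a646_8, df$volume_ml,
                                      df$mass_g, mode = mode))
  df$flagged <- df$chl_a < 0 | df$chl_b < 0 | df$chl_total < 0
  attr(df, "mode") <- mode
  df
}

.chl_check <- function(a663_2, a646_8, volume_ml, mass_g) {
  if (any(a663_2 < 0) || any(a646_8 < 0))
    stop("absorbances must be >= 0")
  if (any(volume_ml <= 0)) stop("'volume_ml' must be > 0")
  if (any(mass_g <= 0)) stop("'mass_g' must be > 0")
}

.flag <- function(x) structure(x, flagged = x < 0)
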