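## Optimal-level claims made in the study's Results prose, per species and
## parameter, as coded levels. These are the reproduction surface: the
## per-parameter rank figures are not machine-readable, the prose is.
.proseClaims <- function() {
  g <- .PARAM_GROUPS$growth   # 7, incl. chlorophyll
  e <- .PARAM_GROUPS$elements # 10
  all <- c(g, e)
  clm <- function(species, parameter, factor, level)
    data.frame(species = species, parameter = parameter, factor = factor,
               claimed_level = level, stringsAsFactors = FALSE)
  rbind(
    clm("lettuce", all, "led", 3L),
    clm("lettuce", g, "ec", 2L),
    clm("lettuce", e, "ec", 3L),
    clm("lettuce", all, "day_temp", 1L),
    clm("lettuce", all, "night_temp", 1L),
    clm("lettuce", c(setdiff(g, "chlorophyll"), "chlorophyll", "N", "P", "Ca"),
        "co2", 2L),
    clm("lettuce", c("Zn", "Cu", "K", "Mg"), "co2", 1L),
    clm("lettuce", c("Fe", "B", "Mn"), "co2", 3L),
    clm("lettuce", c("no_leaf", "leaf_area", "fresh_leaf", "Ca"),
        "humidity", 3L),
    clm("lettuce", setdiff(all, c("no_leaf", "leaf_area", "fresh_leaf", "Ca")),
        "humidity", 2L),
    clm("basil", all, "ec", 3L),
    clm("basil", all, "led", 3L),
    clm("basil", all, "humidity", 2L),
    clm("basil", all, "day_temp", 3L),
    clm("basil", all, "night_temp", 3L),
    clm("basil", g, "co2", 1L),
    clm("basil", setdiff(e, c("Ca", "Fe")), "co2", 3L))
}

#' End-to-end analysis of the packaged study
#'
#' For every measured parameter of the requested species: main-effects
#' table, optimal levels, additive optimum prediction, and two-factor
#' interaction screen. Also compares the computed optimal levels against
#' the optimal-level claims stated in the study's Results prose and marks
#' each claim match/mismatch (the \code{reproduction} element).
#'
#' @param species character vector, subset of
#'   \code{c("lettuce", "basil")}.
#' @param outDir optional directory; when given, writes
#'   \code{main_effects.csv}, \code{best_levels.csv},
#'   \code{predictions.csv}, \code{interactions.csv},
#'   \code{reproduction.json} and \code{metadata.json} (package version and
#'   fixture checksums).
#' @param criterion S/N criterion.
#' @param thresholdFrac interaction-threshold fraction (see
#'   \code{\link{interactionSummary}}).
#' @return (invisibly when writing) a list with data.frames
#'   \code{mainEffects}, \code{bestLevels}, \code{predictions},
#'   \code{interactions}, \code{reproduction}.
#' @importFrom jsonlite write_json
#' @export
runFullAnalysis <- function(species = c("lettuce", "basil"), outDir = NULL,
                            criterion = "larger", thresholdFrac = 0.1) {
  species <- match.arg(species, several.ok = TRUE)
  me_all <- list(); bl_all <- list(); pr_all <- list(); ix_all <- list()
  for (sp in species) {
    te <- loadStudy(sp, "all")
    conf <- confirmationData()
    for (p in rownames(te)) {
      me <- mainEffects(te, p, criterion = criterion)
      tb <- me@table
      tb$species <- sp; tb$parameter <- p; tb$grand_mean <- me@grandMean
      me_all[[paste(sp, p)]] <- tb
      lv <- bestLevels(me)
      bl_all[[paste(sp, p)]] <- data.frame(
        species = sp, parameter = p, factor = names(lv),
        level = as.integer(lv),
        setting = vapply(names(lv), function(f) {
          cat_ <- factorCatalog(te)
          cat_$label[cat_$factor == f & cat_$level == lv[[f]]]
        }, character(1)),
        tie = attr(lv, "tie"), stringsAsFactors = FALSE)
      exp_val <- conf$expected[conf$species == sp & conf$parameter == p]
      op <- predictOptimum(te, p, expected = if (length(exp_val)) exp_val
                                             else NA_real_)
      pr_all[[paste(sp, p)]] <- data.frame(
        species = sp, parameter = p, predicted_sn_db = op@predictedSN,
        predicted_response = op@predictedResponse, expected = op@expected,
        error_pct = op@errorPercent, stringsAsFactors = FALSE)
      ix <- interactionSummary(te, p, thresholdFrac = thresholdFrac,
                               criterion = criterion)
      ix$species <- sp; ix$parameter <- p
      ix_all[[paste(sp, p)]] <- ix
    }
  }
  bl <- do.call(rbind, bl_all); rownames(bl) <- NULL
  repro <- merge(.proseClaims(), bl[c("species", "parameter", "factor", "level")],
                 by = c("species", "parameter", "factor"))
  repro <- repro[repro$species %in% species, ]
  repro$match <- repro$claimed_level == repro$level
  repro <- repro[order(repro$species, repro$parameter, repro$factor), ]
  rownames(repro) <- NULL
  out <- list(mainEffects = do.call(rbind, me_all),
              bestLevels = bl,
              predictions = do.call(rbind, pr_all),
              interactions = do.call(rbind, ix_all),
              reproduction = repro)
  rownames(out$mainEffects) <- rownames(out$predictions) <-
    rownames(out$interactions) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out$mainEffects, file.path(outDir, "main_effects.csv"),
              row.names = FALSE)
    write.csv(out$bestLevels, file.path(outDir, "best_levels.csv"),
              row.names = FALSE)
    write.csv(out$predictions, file.path(outDir, "predictions.csv"),
              row.names = FALSE)
    write.csv(out$interactions, file.path(outDir, "interactions.csv"),
              row.names = FALSE)
    write_json(out$reproduction, file.path(outDir, "reproduction.json"),
               dataframe = "rows", auto_unbox = TRUE, digits = NA)
    fixtures <- list.files(system.file("extdata", package = "taguchiCEA"),
                           full.names = TRUE)
    write_json(list(package = "taguchiCEA",
                    version = as.character(packageVersion("taguchiCEA")),
                    fixture_md5 = as.list(setNames(tools::md5sum(fixtures),
                                                   basename(fixtures)))),
               file.path(outDir, "metadata.json"), auto_unbox = TRUE)
    return(invisible(out))
  }
  out
}

#' Reproduction summary of the study's prose claims
#'
#' Convenience wrapper: runs \code{\link{runFullAnalysis}} and returns only
#' the claim-by-claim match table.
#'
#' @inheritParams runFullAnalysis
#' @return data.frame \code{species, parameter, factor, claimed_level,
#'   level, match}.
#' @export
reproductionReport <- function(species = c("lettuce", "basil")) {
  runFullAnalysis(species = species)$reproduction
}
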