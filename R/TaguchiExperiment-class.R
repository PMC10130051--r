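#' TaguchiExperiment: responses on an orthogonal-array design
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one designed
#' experiment: measured parameters as rows, design runs as columns, the
#' coded factor levels in \code{colData} and the factor catalog plus species
#' in \code{metadata}. The packaged study stores per-run treatment means
#' (three replicates averaged before publication), so each cell carries a
#' single value per (parameter, run).
#'
#' @slot . inherits all slots from SummarizedExperiment.
#' @param responses numeric matrix, parameters x runs, strictly finite.
#' @param design coded integer design matrix with one row per response
#'   column, cells in \code{1:3} (e.g. from \code{\link{l27Design}}).
#' @param species character scalar, e.g. \code{"lettuce"}, \code{"basil"} or
#'   \code{"synthetic"}.
#' @param catalog factor catalog data.frame (see \code{\link{ceaFactorCatalog}}).
#' @param replicateSemantics \code{"mean_of_3"} for the packaged per-run
#'   treatment means, \code{"single"} otherwise.
#' @return a \code{TaguchiExperiment}.
#'
#' @details Accessors: \code{designMatrix(x)} returns the coded integer
#'   design; \code{factorCatalog(x)} the catalog; \code{studySpecies(x)} the
#'   species tag; \code{responses(x)} the response matrix.
#'
#' @aliases TaguchiExperiment designMatrix factorCatalog studySpecies
#'   responses designMatrix,TaguchiExperiment-method
#'   factorCatalog,TaguchiExperiment-method studySpecies,TaguchiExperiment-method
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @exportClass TaguchiExperiment
#' @export
TaguchiExperiment <- function(responses, design, species = "synthetic",
                              catalog = ceaFactorCatalog(),
                              replicateSemantics = c("mean_of_3", "single")) {
  replicateSemantics <- match.arg(replicateSemantics)
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) colnames(responses) <- rownames(design)
  se <- SummarizedExperiment(
    assays = list(response = responses),
    colData = DataFrame(design, row.names = colnames(responses)))
  metadata(se) <- list(species = species, catalog = catalog,
                       factorOrder = colnames(design),
                       replicateSemantics = replicateSemantics)
  new("TaguchiExperiment", se)
}

setClass("TaguchiExperiment", contains = "SummarizedExperiment")

setValidity("TaguchiExperiment", function(object) {
  msg <- character(0)
  dm <- as.matrix(colData(object))
  if (ncol(dm) == 0L) msg <- c(msg, "colData must carry the coded design")
  if (length(dm) && !all(dm %in% 1:3))
    msg <- c(msg, "coded design levels must be in 1:3")
  a <- assay(object)
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
    msg <- c(msg, "responses must be finite numeric values")
  if (is.null(metadata(object)$species))
    msg <- c(msg, "metadata must record the species")
  if (length(msg)) msg else TRUE
})

#' @rdname TaguchiExperiment-class
#' @param x a TaguchiExperiment.
#' @export
responses <- function(x) assay(x, "response")

setMethod("designMatrix", "TaguchiExperiment", function(x) {
  dm <- as.matrix(colData(x)[, metadata(x)$factorOrder, drop = FALSE])
  storage.mode(dm) <- "integer"
  dm
})

setMethod("factorCatalog", "TaguchiExperiment", function(x) metadata(x)$catalog)

setMethod("studySpecies", "TaguchiExperiment", function(x) metadata(x)$species)

setMethod("show", "TaguchiExperiment", function(object) {
  cat("TaguchiExperiment:", metadata(object)$species, "\n")
  cat("  ", nrow(object), "parameter(s) x", ncol(object), "run(s);",
      length(metadata(object)$factorOrder), "factors (",
      paste(metadata(object)$factorOrder, collapse = ", "), ")\n")
  cat("  replicate semantics:", metadata(object)$replicateSemantics, "\n")
})

.PARAM_GROUPS <- list(
  growth = c("no_leaf", "leaf_area", "fresh_leaf", "dry_leaf",
             "fresh_root", "dry_root", "chlorophyll"),
  elements = c("Fe", "Zn", "Cu", "Mn", "N", "P", "K", "Ca", "Mg", "B"))

#' Parameter catalog of the packaged study
#'
#' @return data.frame mapping each measured parameter to its group
#'   (\code{growth}, \code{chlorophyll}, \code{macro_element},
#'   \code{micro_element}) and units.
#' @export
parameterCatalog <- function() {
  data.frame(
    parameter = c(.PARAM_GROUPS$growth, .PARAM_GROUPS$elements),
    group = c(rep("growth", 6), "chlorophyll",
              rep("micro_element", 4), rep("macro_element", 5), "micro_element"),
    units = c("count", "cm^2", "g", "g", "g", "g", "mg g^-1 FW",
              rep("mg kg^-1 DW", 4), "% DW", rep("mg kg^-1 DW", 5)),
    stringsAsFactors = FALSE)
}

#' Load a packaged 27-run response table
#'
#' Reads the transcribed study fixtures (growth parameters + chlorophyll,
#' or micro/macro elements, or both) for one species and assembles them on
#' the L27 design.
#'
#' @param species \code{"lettuce"} or \code{"basil"}.
#' @param group \code{"growth"} (7 parameters incl. chlorophyll),
#'   \code{"elements"} (10 elements) or \code{"all"}.
#' @return a \code{\link{TaguchiExperiment}} with 27 runs.
#' @examples
#' te <- loadStudy("lettuce", "growth")
#' responses(te)["fresh_leaf", "run25"]  # 52.5
#' @export
loadStudy <- function(species = c("lettuce", "basil"),
                      group = c("growth", "elements", "all")) {
  species <- match.arg(species)
  group <- match.arg(group)
  files <- switch(group,
    growth = paste0(species, "_growth.csv"),
    elements = paste0(species, "_elements.csv"),
    all = paste0(species, c("_growth.csv", "_elements.csv")))
  long <- do.call(rbind, lapply(files, function(f) {
    path <- system.file("extdata", f, package = "taguchiCEA", mustWork = TRUE)
    readResponses(path)
  }))
  responseExperiment(long, species = species)
}

#' Assemble a long-format response table onto the L27 design
#'
#' @param long data.frame with columns \code{species,run,parameter,value}
#'   (validated; see \code{\link{readResponses}}).
#' @param species species tag; defaults to the one in \code{long}.
#' @param design coded design matrix; runs missing from \code{long} are
#'   dropped from the design with a warning.
#' @return a \code{\link{TaguchiExperiment}}.
#' @export
responseExperiment <- function(long, species = NULL, design = l27Design()) {
  if (is.null(species)) species <- unique(long$species)
  if (length(species) != 1L)
    stop("response table mixes species: ", paste(species, collapse = ", "))
  params <- unique(long$parameter)
  runs <- sort(unique(long$run))
  missing <- setdiff(seq_len(nrow(design)), runs)
  if (length(missing)) {
    warning("runs absent from response table and dropped: ",
            paste(missing, collapse = ", "))
    design <- design[runs, , drop = FALSE]
  }
  mat <- matrix(NA_real_, nrow = length(params), ncol = length(runs),
                dimnames = list(params, paste0("run", runs)))
  mat[cbind(match(long$parameter, params), match(long$run, runs))] <- long$value
  if (anyNA(mat)) {
    gaps <- which(is.na(mat), arr.ind = TRUE)
    stop("incomplete response table, e.g. parameter '",
         params[gaps[1, 1]], "' missing at ", colnames(mat)[gaps[1, 2]])
  }
  TaguchiExperiment(mat, design, species = species)
}
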