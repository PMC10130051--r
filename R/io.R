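#' Read and validate a long-format response CSV
#'
#' The on-disk schema is `species,run,parameter,value`, one row per
#' (run, parameter) measurement. Validation errors are aggregated and
#' reported with row numbers: unknown columns, non-integer or out-of-range
#' runs, duplicated (run, parameter) pairs, and non-positive values (the
#' larger-is-better S/N criterion used throughout the study requires
#' strictly positive responses).
#'
#' @param path path to a CSV file.
#' @param requirePositive reject values <= 0 (default TRUE).
#' @return validated data.frame with columns
#'   \code{species,run,parameter,value}.
#' @export
readResponses <- function(path, requirePositive = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "run", "parameter", "value")
  if (!identical(sort(intersect(need, names(df))), sort(need)))
    stop("response CSV must have columns ", paste(need, collapse = ","),
         "; got ", paste(names(df), collapse = ","))
  df <- df[need]
  errs <- character(0)
  rowid <- seq_len(nrow(df)) + 1L  # header is line 1
  if (!is.numeric(df$run) || any(df$run != round(df$run)))
    errs <- c(errs, "column 'run' must be integer")
  bad <- which(df$run < 1 | df$run > 27)
  if (length(bad))
    errs <- c(errs, paste0("run outside 1..27 at line(s) ",
                           paste(rowid[bad], collapse = ", ")))
  if (!is.numeric(df$value)) {
    errs <- c(errs, "column 'value' must be numeric")
  } else {
    nn <- which(!is.finite(df$value) | (requirePositive & df$value <= 0))
    if (length(nn))
      errs <- c(errs, paste0("non-positive or non-finite value at line(s) ",
                             paste(rowid[nn], collapse = ", ")))
  }
  key <- paste(df$species, df$run, df$parameter)
  dup <- which(duplicated(key))
  if (length(dup))
    errs <- c(errs, paste0("duplicated (run, parameter) pair at line(s) ",
                           paste(rowid[dup], collapse = ", "), " [e.g. run ",
                           df$run[dup[1]], ", ", df$parameter[dup[1]], "]"))
  if (length(errs))
    stop("invalid response table '", path, "':\n  ",
         paste(errs, collapse = "\n  "))
  df
}

#' @rdname readResponses
#' @param x long-format response data.frame or a
#'   \code{\link{TaguchiExperiment}}.
#' @export
writeResponses <- function(x, path) {
  if (is(x, "TaguchiExperiment")) {
    m <- responses(x)
    x <- data.frame(species = studySpecies(x),
                    run = rep(as.integer(sub("run", "", colnames(m))),
                              each = nrow(m)),
                    parameter = rep(rownames(m), times = ncol(m)),
                    value = as.vector(m))
  }
  write.csv(x[c("species", "run", "parameter", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
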