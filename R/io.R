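#' Write a result table as CSV with a provenance header
#'
#' Every output file carries a comment header block (lines starting `#`)
#' recording the tool version, the configuration hash, the seed, and any
#' tolerance values relevant to the table.
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @param meta Named list written into the header.
#' @export
write_trc_csv <- function(x, path, meta = list()) {
  meta <- c(list(tool = paste0("trcfit ",
                               as.character(utils::packageVersion("trcfit"))),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
               con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_trc_csv()]
#'
#' @param path CSV path; header comment lines are skipped.
#' @return data.frame.
#' @export
read_trc_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and validate a catchment table
#'
#' @param path CSV with at least `catchment_id`, `latitude` and one
#'   temperature column.
#' @return Validated data.frame.
#' @export
read_catchments <- function(path) {
  x <- read_trc_csv(path)
  need <- c("catchment_id", "latitude")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("catchment table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  if (anyDuplicated(x$catchment_id))
    stopf("catchment table %s has duplicate catchment ids", path)
  x$catchment_id <- as.character(x$catchment_id)
  x
}

#' Read and validate an occurrence table
#'
#' Duplicate (species, catchment) rows are collapsed with a warning;
#' occurrences referencing catchments outside the study universe are an
#' error listing the offenders.
#'
#' @param path CSV with `species_id` and `catchment_id` columns.
#' @param catchments Optional catchment table defining the universe.
#' @return Long-format data.frame.
#' @export
read_occurrences <- function(path, catchments = NULL) {
  x <- read_trc_csv(path)
  need <- c("species_id", "catchment_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("occurrence table %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  x$species_id <- as.character(x$species_id)
  x$catchment_id <- as.character(x$catchment_id)
  dup <- duplicated(x[c("species_id", "catchment_id")])
  if (any(dup)) {
    warnf("collapsed %d duplicate (species, catchment) occurrence rows",
          sum(dup))
    x <- x[!dup, , drop = FALSE]
  }
  if (!is.null(catchments)) {
    unknown <- setdiff(unique(x$catchment_id), catchments$catchment_id)
    if (length(unknown))
      stopf("occurrences reference unknown catchment id(s): %s",
            paste(utils::head(unknown, 10), collapse = ", "))
  }
  x
}
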