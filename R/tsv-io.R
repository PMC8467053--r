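# All tabular results are written as TSV (tab separators, '.' decimal, UTF-8)
# with an optional '#'-prefixed provenance header.

#' Write a results table as TSV
#'
#' @param df data.frame to write
#' @param path output path
#' @param provenance optional named list written as `# key: value` header
#'   lines (e.g. seed, config hash)
#' @return `path`, invisibly
#' @export
write_results_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#' @param path input path
#' @return data.frame (provenance header lines are skipped)
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a master peak list as TSV
#'
#' One row per master-list mass with its provenance flags (which source lists
#' it came from, contributing biological samples, gate outcomes) and
#' whole-dataset CV when present. An empty list produces a header-only file
#' with a warning.
#'
#' @param master master peak list data.frame (column `mz` required)
#' @param path output path
#' @param provenance optional provenance header, see [write_results_tsv()]
#' @return `path`, invisibly
#' @export
write_peaklist_tsv <- function(master, path, provenance = NULL) {
  stopifnot(is.data.frame(master), "mz" %in% names(master))
  if (nrow(master) == 0) {
    warning("writing empty peak list (header only): ", path)
  }
  num <- vapply(master, is.numeric, logical(1))
  master[num] <- lapply(master[num], function(x) round(x, 6))
  write_results_tsv(master, path, provenance)
}

#' Read a master peak list TSV
#' @param path input path
#' @return data.frame as written by [write_peaklist_tsv()]
#' @export
read_peaklist_tsv <- function(path) {
  read_results_tsv(path)
}
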