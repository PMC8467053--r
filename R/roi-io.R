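#' Read a per-pixel ROI label mask
#'
#' The CSV must have columns `x`, `y`, `label` with labels from the closed set
#' `tumor`, `necrosis`, `off_tissue`, `excluded` (0-based grid coordinates).
#' Pixels of the dataset absent from the CSV default to `excluded`; CSV rows
#' for pixels not present in the dataset grid are an error, as is any unknown
#' label.
#'
#' @param path path to the ROI CSV
#' @param dataset the [msi_dataset()] the mask belongs to
#' @return factor of labels aligned with `dataset$coords`
#' @export
read_roi_mask <- function(path, dataset) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "label") %in% names(df)))
  bad <- which(!df$label %in% .ROI_LEVELS)
  if (length(bad)) {
    stop("unknown ROI label '", df$label[bad[1]], "' in row ", bad[1],
         " of ", path)
  }
  key <- paste(dataset$coords$x, dataset$coords$y)
  idx <- match(paste(df$x, df$y), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("ROI row ", miss, " labels pixel (", df$x[miss], ",", df$y[miss],
         ") absent from the dataset grid")
  }
  roi <- rep("excluded", n_pixels(dataset))
  roi[idx] <- df$label
  factor(roi, levels = .ROI_LEVELS)
}

#' Write a per-pixel ROI label mask
#' @param dataset an [msi_dataset()] with attached labels
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_roi_mask <- function(dataset, path) {
  utils::write.csv(
    data.frame(x = dataset$coords$x, y = dataset$coords$y,
               label = as.character(dataset$roi)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach an ROI mask to a dataset
#' @param dataset an [msi_dataset()]
#' @param roi factor/character of labels, one per pixel
#' @return the dataset with `roi` replaced
#' @export
attach_roi <- function(dataset, roi) {
  dataset$roi <- validate_roi_labels(as.character(roi), n_pixels(dataset))
  dataset
}

#' Read per-section metadata from YAML
#'
#' Expected keys: `section_id`, `bio_sample`, `tech_rep` (1..3), `arm`
#' (`treated`/`control`), optional `day`.
#'
#' @param path YAML path
#' @return validated metadata list
#' @export
read_section_meta <- function(path) {
  validate_section_meta(yaml::read_yaml(path))
}

#' Write per-section metadata as YAML
#' @param meta metadata list (see [read_section_meta()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_section_meta <- function(meta, path) {
  yaml::write_yaml(validate_section_meta(meta), path)
  invisible(path)
}
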