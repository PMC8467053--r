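#' Reference result tables bundled with the package
#'
#' The master peak list, tumor-vs-necrosis LMM results and treated-vs-control
#' marker table reported by the original FFPE xenograft study, transcribed as
#' TSV. They serve as worked-example inputs: counting and threshold rules can
#' be exercised against them, and the accurate-mass annotations can be
#' recomputed from the bundled lipid table.
#'
#' @param which one of `"master_list"`, `"tumor_necrosis"`,
#'   `"treatment_markers"`
#' @return data.frame
#' @export
reference_table <- function(which = c("master_list", "tumor_necrosis",
                                      "treatment_markers")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".tsv"),
                      package = "lipidmsi")
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df
}
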