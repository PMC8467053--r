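# Monoisotopic masses of the most abundant isotope (IUPAC/CODATA), Da.
.MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928
)

# Electron rest mass, Da. Subtracted from cation adduct deltas so sodium
# adducts of ~800 Da lipids stay sub-ppm (0.55 mDa ~ 0.7 ppm at m/z 800).
.ELECTRON_MASS <- 0.00054857990907

# Cation adduct mass deltas (Da), electron loss included.
.ADDUCT_DELTA <- c(
  "[M+H]+"      = 1.0078250319 - 0.00054857990907,
  "[M+Na]+"     = 22.98976928 - 0.00054857990907,
  "[M+H-H2O]+"  = 1.0078250319 - 18.0105646863 - 0.00054857990907
)

#' Normalise an adduct label to the canonical ASCII spelling
#'
#' Accepts spacing and unicode-minus variants such as `"[M + Na]+"` or
#' `"[M+H−H2O]+"`.
#' @param label character adduct label(s)
#' @return canonical label(s), one of `names(lipidmsi:::.ADDUCT_DELTA)`
#' @keywords internal
normalize_adduct <- function(label) {
  x <- gsub("−", "-", label)
  x <- gsub("[[:space:]]", "", x)
  x <- gsub("\\^\\+", "+", x)
  x
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope masses over a condensed formula string such as
#' `"C43H78NO8P"`. Supported elements: C, H, N, O, P, S, Na. An element symbol
#' without a count means count 1; the empty formula has mass 0.
#'
#' @param formula character scalar, e.g. `"C39H76NO8P"`
#' @return monoisotopic mass in Da
#' @examples
#' monoisotopic_mass("H2O")         # 18.010565
#' monoisotopic_mass("C43H78NO8P")  # PE 38:4 neutral mass
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (is.na(formula) || formula == "") return(0)
  if (grepl("[^A-Za-z0-9]", formula)) {
    stop("formula contains unsupported characters: ", formula)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("formula does not parse: ", formula)
  }
  total <- 0
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (cnt == "") 1L else as.integer(cnt)
    if (!sym %in% names(.MONOISOTOPIC_MASS)) {
      stop("unknown element symbol '", sym, "' in formula ", formula)
    }
    total <- total + .MONOISOTOPIC_MASS[[sym]] * n
  }
  total
}

#' Theoretical m/z of a singly charged adduct
#'
#' @param M neutral monoisotopic mass (Da), `M > 0`
#' @param adduct adduct label: `"[M+H]+"`, `"[M+Na]+"` or `"[M+H-H2O]+"`
#'   (spacing/unicode variants accepted)
#' @return theoretical m/z in Da (electron mass accounted for)
#' @examples
#' adduct_mz(monoisotopic_mass("C39H76NO8P"), "[M+Na]+")  # 740.520
#' @export
adduct_mz <- function(M, adduct) {
  stopifnot(is.numeric(M), all(M > 0))
  key <- normalize_adduct(adduct)
  if (!key %in% names(.ADDUCT_DELTA)) {
    stop("unsupported adduct label: ", adduct)
  }
  M + .ADDUCT_DELTA[[key]]
}

#' Signed ppm mass error
#'
#' @param observed observed m/z (Da)
#' @param theoretical theoretical m/z (Da), `> 0`
#' @return `(observed - theoretical) / theoretical * 1e6`
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Load the bundled lipid reference table
#'
#' A TSV of glycerophospholipid and sphingomyelin species (name, class,
#' elemental formula, allowed adducts, flags), combining the species the
#' annotated master list reports with a decoy set of common lipids, for
#' offline accurate-mass matching.
#'
#' @param path optional path to an alternative table with the same columns
#' @return data.frame with columns `name`, `class`, `formula`, `adducts`
#'   (semicolon-separated labels), `theoretical_only` (logical), `note`
#' @export
load_lipid_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_reference.tsv", package = "lipidmsi")
  }
  stopifnot(file.exists(path))
  db <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  db$theoretical_only <- as.logical(db$theoretical_only)
  db
}

#' Annotate observed m/z values by accurate mass
#'
#' Every (lipid, adduct) candidate whose theoretical m/z lies within
#' `tol_ppm` of an observed mass is reported, ranked by absolute ppm error.
#' Identification tiers follow the accurate-mass confidence bands used for
#' FT-ICR annotation: `sub_ppm` (< 1 ppm), `loose` (8--10 ppm), `within_10`
#' (anything else inside tolerance); observed masses with no candidate get a
#' single `tier = "none"` row.
#'
#' @param observed_mz numeric vector of observed m/z values
#' @param db lipid table as returned by [load_lipid_table()]
#' @param adducts adduct labels to consider; defaults to each record's own
#'   `adducts` column
#' @param tol_ppm matching tolerance in ppm (default 10)
#' @return data.frame with one row per (observed_mz, candidate):
#'   `observed_mz`, `name`, `class`, `adduct`, `formula`, `theoretical_mz`,
#'   `ppm`, `tier`, `rank`
#' @export
match_lipids <- function(observed_mz, db = load_lipid_table(), adducts = NULL,
                         tol_ppm = 10) {
  stopifnot(nrow(db) > 0, tol_ppm >= 0)
  # expand candidate (record, adduct) pairs once
  cand <- do.call(rbind, lapply(seq_len(nrow(db)), function(i) {
    labs <- if (is.null(adducts)) {
      strsplit(db$adducts[i], ";", fixed = TRUE)[[1]]
    } else {
      adducts
    }
    labs <- normalize_adduct(trimws(labs))
    labs <- labs[labs %in% names(.ADDUCT_DELTA)]
    if (!length(labs)) return(NULL)
    M <- monoisotopic_mass(db$formula[i])
    data.frame(name = db$name[i], class = db$class[i], adduct = labs,
               formula = db$formula[i],
               theoretical_mz = M + unname(.ADDUCT_DELTA[labs]),
               stringsAsFactors = FALSE)
  }))
  out <- lapply(observed_mz, function(mz) {
    ppm <- ppm_error(mz, cand$theoretical_mz)
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) {
      return(data.frame(observed_mz = mz, name = NA_character_,
                        class = NA_character_, adduct = NA_character_,
                        formula = NA_character_, theoretical_mz = NA_real_,
                        ppm = NA_real_, tier = "none", rank = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    hit <- hit[order(abs(ppm[hit]))]
    res <- cand[hit, , drop = FALSE]
    res$observed_mz <- mz
    res$ppm <- ppm[hit]
    res$tier <- ifelse(abs(res$ppm) < 1, "sub_ppm",
                ifelse(abs(res$ppm) >= 8 & abs(res$ppm) <= 10, "loose",
                       "within_10"))
    res$rank <- seq_len(nrow(res))
    res[, c("observed_mz", "name", "class", "adduct", "formula",
            "theoretical_mz", "ppm", "tier", "rank")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Annotate a master peak list with lipid identifications
#'
#' Adds the best accurate-mass hit (if any) per master-list mass.
#'
#' @param master data.frame with an `mz` column (a master peak list)
#' @param db lipid table, see [load_lipid_table()]
#' @param tol_ppm matching tolerance in ppm
#' @return `master` with columns `id`, `adduct`, `theoretical_mz`, `ppm`,
#'   `tier` appended
#' @export
annotate_master_list <- function(master, db = load_lipid_table(), tol_ppm = 10) {
  stopifnot(is.data.frame(master), "mz" %in% names(master))
  hits <- match_lipids(master$mz, db = db, tol_ppm = tol_ppm)
  best <- hits[is.na(hits$rank) | hits$rank == 1L, , drop = FALSE]
  best <- best[match(master$mz, best$observed_mz), , drop = FALSE]
  master$id <- best$name
  master$adduct <- best$adduct
  master$theoretical_mz <- best$theoretical_mz
  master$ppm <- best$ppm
  master$tier <- best$tier
  master
}
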