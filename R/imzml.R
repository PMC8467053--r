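# Minimal imzML 1.1 reader/writer (continuous and processed mode).
# An imzML dataset is an XML part (<name>.imzML) describing per-spectrum
# coordinates and external-array byte offsets into a binary part (<name>.ibd)
# that starts with a 16-byte UUID. Arrays are stored as little-endian
# 64-bit floats.

.ibd_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".ibd")
}

#' Read an imzML file pair
#'
#' Parses `<path>` (the XML part) together with its `.ibd` binary companion
#' and returns the pixel spectra with imzML's 1-based pixel coordinates mapped
#' to the internal 0-based grid.
#'
#' @param path path to the `.imzML` file; the `.ibd` file must sit alongside
#' @return an [msi_dataset()]; continuous-mode files yield a shared m/z axis,
#'   processed-mode files keep per-pixel axes
#' @export
read_imzml <- function(path) {
  stopifnot(file.exists(path))
  ibd <- .ibd_path(path)
  if (!file.exists(ibd)) stop("missing .ibd companion for ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//fileDescription/fileContent/cvParam"),
    "accession")
  mode <- if ("IMS:1000030" %in% acc) "continuous"
          else if ("IMS:1000031" %in% acc) "processed"
          else stop("file declares neither continuous nor processed mode")

  spectra <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (!length(spectra)) stop("no spectra in ", path)

  get_pos <- function(sp, accession) {
    node <- xml2::xml_find_first(
      sp, sprintf(".//scan/cvParam[@accession='%s']", accession))
    as.integer(xml2::xml_attr(node, "value"))
  }
  get_array <- function(sp, group) {
    bda <- xml2::xml_find_first(
      sp, sprintf(".//binaryDataArray[referenceableParamGroupRef/@ref='%s']",
                  group))
    cv <- function(a) as.numeric(xml2::xml_attr(xml2::xml_find_first(
      bda, sprintf(".//cvParam[@accession='%s']", a)), "value"))
    c(length = cv("IMS:1000103"), offset = cv("IMS:1000102"))
  }

  con <- file(ibd, "rb")
  on.exit(close(con))
  read_doubles <- function(offset, n) {
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = n, size = 8, endian = "little")
  }

  n <- length(spectra)
  xs <- ys <- integer(n)
  mz_list <- int_list <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    xs[i] <- get_pos(sp, "IMS:1000050") - 1L  # imzML is 1-based
    ys[i] <- get_pos(sp, "IMS:1000051") - 1L
    mz_arr <- get_array(sp, "mzArray")
    int_arr <- get_array(sp, "intensityArray")
    mz_list[[i]] <- read_doubles(mz_arr["offset"], mz_arr["length"])
    int_list[[i]] <- read_doubles(int_arr["offset"], int_arr["length"])
    if (length(mz_list[[i]]) > 1 && any(diff(mz_list[[i]]) <= 0)) {
      stop("non-monotone m/z axis in spectrum ", i)
    }
  }
  coords <- data.frame(x = xs, y = ys)
  if (mode == "continuous") {
    msi_dataset(mz_list[[1]], do.call(rbind, int_list), coords)
  } else {
    msi_dataset(mz_list, int_list, coords)
  }
}

#' Write an imzML file pair
#'
#' Writes `dataset` as `<path>` plus the `.ibd` binary companion, in the
#' dataset's own storage mode. Internal 0-based coordinates are emitted using
#' imzML's 1-based convention, so [read_imzml()] round-trips bit-identically.
#'
#' @param dataset an [msi_dataset()]
#' @param path output `.imzML` path
#' @return `path`, invisibly
#' @export
write_imzml <- function(dataset, path) {
  ibd <- .ibd_path(path)
  uuid <- as.raw(c(0x6c, 0x69, 0x70, 0x69, 0x64, 0x6d, 0x73, 0x69,
                   sample.int(256L, 8L, replace = TRUE) - 1L))
  con <- file(ibd, "wb")
  writeBin(uuid, con)
  offset <- 16
  n_pix <- n_pixels(dataset)

  put <- function(v) {
    writeBin(as.double(v), con, size = 8, endian = "little")
    start <- offset
    offset <<- offset + 8 * length(v)
    c(length = length(v), offset = start, encoded = 8 * length(v))
  }

  if (dataset$mode == "continuous") {
    mz_ref <- put(dataset$mz)
    arr <- lapply(seq_len(n_pix), function(i) {
      list(mz = mz_ref, int = put(dataset$intensity[i, ]))
    })
  } else {
    arr <- lapply(seq_len(n_pix), function(i) {
      list(mz = put(dataset$mz[[i]]), int = put(dataset$intensity[[i]]))
    })
  }
  close(con)

  mode_param <- if (dataset$mode == "continuous") {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>'
  }
  bda <- function(group, a) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="', group, '"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', a["length"]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>', a["offset"]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', a["encoded"]),
      "<binary/></binaryDataArray>")
  }
  spectra <- vapply(seq_len(n_pix), function(i) {
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, arr[[i]]$int["length"]),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
              dataset$coords$x[i] + 1L),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
              dataset$coords$y[i] + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      bda("mzArray", arr[[i]]$mz), bda("intensityArray", arr[[i]]$int),
      "</binaryDataArrayList></spectrum>")
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    "<fileDescription><fileContent>",
    mode_param,
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            paste(sprintf("%02x", as.integer(uuid)), collapse = "")),
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    "</referenceableParamGroup></referenceableParamGroupList>",
    '<run id="run1"><spectrumList count="', n_pix, '">',
    paste(spectra, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, path)
  invisible(path)
}
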