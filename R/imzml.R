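# Continuous-mode imzML reading and writing.  imzML splits an acquisition
# into an XML index (.imzML) and a raw binary blob (.ibd) addressed by
# byte offsets; in continuous mode one shared m/z axis is stored once and
# every pixel stores only its intensity vector.

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

# byte width by mzML binary-type accession
IMZML_DTYPES <- c("MS:1000523" = 8, "MS:1000521" = 4)

cv_value <- function(node, accession) {
  hit <- xml2::xml_find_first(node, sprintf(
    ".//*[local-name()='cvParam'][@accession='%s']", accession))
  if (inherits(hit, "xml_missing")) NA_character_
  else xml2::xml_attr(hit, "value")
}

#' Read a continuous-mode imzML file
#'
#' Parses the XML index, checks that the file is continuous mode (one
#' shared m/z axis; processed mode, with per-pixel axes, is rejected),
#' and reads the binary arrays from the sibling `.ibd` file. All spectra
#' must reference the identical m/z array.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to
#'   it).
#' @return An [msi_dataset()] with the pixel coordinates as recorded in
#'   the file (1-based imzML convention; missing z positions become 1)
#'   and `meta$normalized = FALSE`.
#' @seealso [write_imzml()]
#' @export
read_imzml <- function(path) {
  p <- imzml_paths(path)
  if (!file.exists(p$xml)) stop("no such file: ", p$xml, call. = FALSE)
  if (!file.exists(p$ibd))
    stop("missing binary file: ", p$ibd, call. = FALSE)
  doc <- xml2::read_xml(p$xml)

  fc <- xml2::xml_find_first(doc, "//*[local-name()='fileContent']")
  mode_acc <- xml2::xml_attr(xml2::xml_find_all(
    fc, ".//*[local-name()='cvParam']"), "accession")
  if ("IMS:1000031" %in% mode_acc)
    stop(paste("unsupported imzML format: processed mode (per-pixel m/z",
               "axes); only continuous mode is supported"), call. = FALSE)
  if (!"IMS:1000030" %in% mode_acc)
    stop("imzML file does not declare continuous mode", call. = FALSE)

  # dtype per referenceable param group
  groups <- xml2::xml_find_all(
    doc, "//*[local-name()='referenceableParamGroup']")
  group_width <- list()
  group_role <- list()
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    accs <- xml2::xml_attr(
      xml2::xml_find_all(g, ".//*[local-name()='cvParam']"), "accession")
    w <- IMZML_DTYPES[intersect(names(IMZML_DTYPES), accs)]
    if (length(w)) group_width[[id]] <- unname(w[1])
    if ("MS:1000514" %in% accs) group_role[[id]] <- "mz"
    if ("MS:1000515" %in% accs) group_role[[id]] <- "intensity"
  }

  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  n <- length(spectra)
  if (n == 0) stop("imzML file contains no spectra", call. = FALSE)

  coords <- matrix(1L, n, 3)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    x <- cv_value(sp, "IMS:1000050")
    y <- cv_value(sp, "IMS:1000051")
    z <- cv_value(sp, "IMS:1000052")
    coords[i, 1] <- as.integer(x)
    coords[i, 2] <- as.integer(y)
    if (!is.na(z)) coords[i, 3] <- as.integer(z)

    arrays <- xml2::xml_find_all(
      sp, ".//*[local-name()='binaryDataArray']")
    rec <- list()
    for (a in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(
        a, ".//*[local-name()='referenceableParamGroupRef']"), "ref")
      role <- group_role[[ref]]
      if (is.null(role)) next
      rec[[role]] <- list(
        offset = as.numeric(cv_value(a, "IMS:1000102")),
        length = as.integer(cv_value(a, "IMS:1000103")),
        width = group_width[[ref]])
    }
    if (is.null(rec$mz) || is.null(rec$intensity))
      stop(sprintf("spectrum %d lacks m/z or intensity array metadata", i),
           call. = FALSE)
    info[[i]] <- rec
  }

  mz_off <- vapply(info, function(r) r$mz$offset, numeric(1))
  mz_len <- vapply(info, function(r) r$mz$length, integer(1))
  if (any(mz_off != mz_off[1]) || any(mz_len != mz_len[1])) {
    bad <- which(mz_off != mz_off[1] | mz_len != mz_len[1])[1]
    stop(sprintf(
      "m/z axis mismatch across spectra (first offending pixel: %d); %s",
      bad, "continuous mode requires one shared axis"), call. = FALSE)
  }

  con <- file(p$ibd, "rb")
  on.exit(close(con))
  seek(con, mz_off[1])
  mz <- readBin(con, "double", n = mz_len[1], size = info[[1]]$mz$width)
  d <- mz_len[1]
  intens <- matrix(0, n, d)
  for (i in seq_len(n)) {
    r <- info[[i]]$intensity
    if (r$length != d)
      stop(sprintf("spectrum %d has %d intensities but the axis has %d",
                   i, r$length, d), call. = FALSE)
    seek(con, r$offset)
    intens[i, ] <- readBin(con, "double", n = d, size = r$width)
  }

  ds <- msi_dataset(mz = mz, intensities = intens, coords = coords,
                    source = p$xml)
  empty <- which(rowSums(ds$intensities) == 0)
  if (length(empty)) ds$meta$empty_pixels <- empty
  stop_if_invalid(ds)
}

imzml_header <- function(uuid, n, d, mz_bytes, int_bytes, max_x, max_y) {
  mz_prec <- if (mz_bytes == 8)
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>'
  int_prec <- if (int_bytes == 8)
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>'
  sprintf('<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
 <cvList count="3">
  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
  <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>
  <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>
 </cvList>
 <fileDescription>
  <fileContent>
   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
  </fileContent>
 </fileDescription>
 <referenceableParamGroupList count="2">
  <referenceableParamGroup id="mzArray">
   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
   %s
   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
  </referenceableParamGroup>
  <referenceableParamGroup id="intensityArray">
   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
   %s
   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
  </referenceableParamGroup>
 </referenceableParamGroupList>
 <scanSettingsList count="1">
  <scanSettings id="scanSettings0">
   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
  </scanSettings>
 </scanSettingsList>
 <instrumentConfigurationList count="1">
  <instrumentConfiguration id="IC0"/>
 </instrumentConfigurationList>
 <run id="run0">
  <spectrumList count="%d">
', uuid, mz_prec, int_prec, max_x, max_y, n)
}

imzml_spectrum_entry <- function(i, coord, d, mz_off, mz_enc, int_off,
                                 int_enc) {
  sprintf('   <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">
    <scanList count="1">
     <scan>
      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000052" name="position z" value="%d"/>
     </scan>
    </scanList>
    <binaryDataArrayList count="2">
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="mzArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>
      <binary/>
     </binaryDataArray>
     <binaryDataArray encodedLength="0">
      <referenceableParamGroupRef ref="intensityArray"/>
      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>
      <binary/>
     </binaryDataArray>
    </binaryDataArrayList>
   </spectrum>
', i, i - 1L, d, coord[1], coord[2], coord[3], d, mz_off, mz_enc, d,
    int_off, int_enc)
}

#' Write a continuous-mode imzML file
#'
#' Writes the XML index and the binary `.ibd` with the shared m/z axis
#' stored once followed by one intensity vector per pixel.
#'
#' @param ds An [msi_dataset()]; validated before writing.
#' @param path Output `.imzML` path (the `.ibd` is written next to it).
#' @param intensity_dtype `"float32"` (default) or `"float64"` storage
#'   for intensities; the m/z axis is always stored as 64-bit floats.
#' @return The `.imzML` path, invisibly.
#' @export
write_imzml <- function(ds, path, intensity_dtype = c("float32",
                                                      "float64")) {
  intensity_dtype <- match.arg(intensity_dtype)
  stop_if_invalid(ds)
  p <- imzml_paths(path)
  int_bytes <- if (intensity_dtype == "float64") 8L else 4L
  n <- nrow(ds$intensities)
  d <- length(ds$mz)

  uuid_raw <- as.raw(sample.int(256, 16, replace = TRUE) - 1L)
  hex <- paste0(format(uuid_raw), collapse = "")
  uuid <- toupper(paste(substr(hex, 1, 8), substr(hex, 9, 12),
                        substr(hex, 13, 16), substr(hex, 17, 20),
                        substr(hex, 21, 32), sep = "-"))

  mz_off <- 16
  mz_enc <- d * 8
  int_off0 <- mz_off + mz_enc
  int_enc <- d * int_bytes

  con <- file(p$ibd, "wb")
  writeBin(uuid_raw, con)
  writeBin(as.numeric(ds$mz), con, size = 8)
  for (i in seq_len(n))
    writeBin(as.numeric(ds$intensities[i, ]), con, size = int_bytes)
  close(con)

  xml <- file(p$xml, "w")
  cat(imzml_header(uuid, n, d, 8L, int_bytes,
                   max(ds$coords[, 1]), max(ds$coords[, 2])), file = xml)
  for (i in seq_len(n))
    cat(imzml_spectrum_entry(i, ds$coords[i, ], d, mz_off, mz_enc,
                             int_off0 + (i - 1) * int_enc, int_enc),
        file = xml)
  cat("  </spectrumList>\n </run>\n</mzML>\n", file = xml)
  close(xml)
  invisible(p$xml)
}
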