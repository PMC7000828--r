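#' Read spectra from disk
#'
#' Supported formats: `"csv"` (two columns, m/z and intensity, one file per
#' spectrum; a directory of such files is read as a list), `"mzml"` (one file
#' holding one spectrum per spot) and `"smx"` (the package's plain-text
#' spectral-matrix container: a directory with `meta.json`, `grid.csv`,
#' `matrix.csv` and `offsets.csv`). Non-ascending m/z values are repaired by
#' sorting with a warning.
#'
#' @param path File or directory path.
#' @param format One of `"auto"`, `"csv"`, `"mzml"`, `"smx"`.
#' @return A `mass_spectrum`, a list of them (csv directory, mzML), or a
#'   `spectral_matrix` (smx).
#' @export
read_spectra <- function(path, format = c("auto", "csv", "mzml", "smx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      if (file.exists(file.path(path, "meta.json"))) "smx" else "csv"
    } else switch(tolower(tools::file_ext(path)), mzml = "mzml", csv = "csv",
                  stop("cannot infer format of ", path))
  }
  switch(format,
    csv = if (dir.exists(path)) {
      files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
      lapply(seq_along(files), function(i) {
        s <- read_spectrum_csv(files[i]); s$spot_id <- i; s
      })
    } else read_spectrum_csv(path),
    mzml = read_mzml(path),
    smx = read_smx(path))
}

read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2L) stop("spectrum CSV needs two columns (m/z, intensity)")
  mass_spectrum(df[[1]], df[[2]])
}

#' Write spectra to disk
#'
#' @param spectra A `mass_spectrum` or list of them.
#' @param path Output file (csv/mzML) or directory (csv list).
#' @param format `"csv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("csv", "mzml")) {
  format <- match.arg(format)
  single <- inherits(spectra, "mass_spectrum")
  if (format == "csv") {
    if (single) {
      write.csv(data.frame(mz = spectra$mz, intensity = spectra$intensity),
                path, row.names = FALSE)
    } else {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(spectra)) {
        write.csv(data.frame(mz = spectra[[i]]$mz,
                             intensity = spectra[[i]]$intensity),
                  file.path(path, sprintf("spot%05d.csv", i)),
                  row.names = FALSE)
      }
    }
  } else {
    write_mzml(if (single) list(spectra) else spectra, path)
  }
  invisible(path)
}

# --- minimal mzML writer/reader -------------------------------------------
# 64-bit little-endian float arrays, uncompressed, base64; the layout follows
# the PSI mzML 1.1 schema closely enough for standard readers.

encode_b64_doubles <- function(x) {
  # jsonlite wraps base64 lines; mzML consumers expect one unbroken token
  gsub("[\r\n]", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L,
                                                   endian = "little")))
}

decode_b64_doubles <- function(s, n) {
  readBin(jsonlite::base64_dec(gsub("[\r\n ]", "", s)), "numeric", n = n,
          size = 8L, endian = "little")
}

write_mzml <- function(spectra, path) {
  n <- length(spectra)
  bda <- function(data, cv_acc, cv_name) {
    b64 <- encode_b64_doubles(data)
    paste0(
      '<binaryDataArray encodedLength="', nchar(b64), '">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="', cv_acc, '" name="', cv_name,
      '" unitCvRef="MS"/>', '<binary>', b64, '</binary></binaryDataArray>')
  }
  specs <- vapply(seq_len(n), function(i) {
    s <- spectra[[i]]
    paste0(
      '<spectrum index="', i - 1L, '" id="spot=', i,
      '" defaultArrayLength="', length(s$mz), '">',
      '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>',
      '<binaryDataArrayList count="2">',
      bda(s$mz, "MS:1000514", "m/z array"),
      bda(s$intensity, "MS:1000515", "intensity array"),
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="ugimem" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="ugimem"/>',
    '</dataProcessingList_placeholder>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="', n, '" defaultDataProcessingRef="dp1">',
    paste(specs, collapse = ""),
    '</spectrumList></run></mzML>\n')
  xml <- sub('</dataProcessingList_placeholder>',
             '</dataProcessing></dataProcessingList>', xml, fixed = TRUE)
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrum")
  lapply(seq_along(nodes), function(i) {
    node <- nodes[[i]]
    len <- as.integer(xml2::xml_attr(node, "defaultArrayLength"))
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    vals <- lapply(arrays, function(a) {
      acc <- xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "accession")
      if (any(acc == "MS:1000574")) stop("zlib-compressed mzML not supported")
      kind <- if (any(acc == "MS:1000514")) "mz"
              else if (any(acc == "MS:1000515")) "intensity" else NA
      b64 <- xml2::xml_text(xml2::xml_find_first(a, ".//binary"))
      list(kind = kind, data = decode_b64_doubles(b64, len))
    })
    kinds <- vapply(vals, `[[`, "", "kind")
    mass_spectrum(vals[[which(kinds == "mz")]]$data,
                  vals[[which(kinds == "intensity")]]$data, spot_id = i)
  })
}

# --- spectral-matrix container --------------------------------------------

#' Write a spectral matrix container
#'
#' Writes the analysis-ready matrix as a plain-text directory container:
#' `meta.json` (dimensions, SNR flag, spot ids), `grid.csv` (common m/z
#' grid), `matrix.csv` (one row per spot) and `offsets.csv` (per-spot
#' calibration offsets, ppm). Read back with [read_spectra()] or
#' [read_smx()].
#'
#' @param smat A `spectral_matrix`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_spectral_matrix <- function(smat, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(container = "ugimem-spectral-matrix", version = 1L,
         n_spots = nrow(smat$mat), n_grid = length(smat$grid),
         snr = smat$snr, spot_ids = smat$spot_ids),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(mz = smat$grid), file.path(path, "grid.csv"),
            row.names = FALSE)
  write.table(smat$mat, file.path(path, "matrix.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.csv(data.frame(spot = smat$spot_ids, offset_ppm = smat$offsets_ppm),
            file.path(path, "offsets.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectral_matrix
#' @export
read_smx <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  grid <- read.csv(file.path(path, "grid.csv"))$mz
  mat <- as.matrix(read.csv(file.path(path, "matrix.csv"), header = FALSE))
  dimnames(mat) <- NULL
  off <- read.csv(file.path(path, "offsets.csv"))
  spectral_matrix(grid, mat, spot_ids = meta$spot_ids,
                  offsets_ppm = off$offset_ppm, snr = isTRUE(meta$snr))
}
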