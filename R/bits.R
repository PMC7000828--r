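#' Flatten a bilevel image into a bit vector
#'
#' Reads a binary (bilevel) raster and flattens it row-major into bits, using
#' the convention white = 0, black = 1. Accepts a 0/1 matrix (1 = black), a
#' PNG path (grayscale or RGB, values must be exactly black/white) or an
#' ASCII PBM (`P1`) path.
#'
#' @param image Matrix or file path.
#' @return Integer bit vector with attribute `dim` = c(rows, cols).
#' @export
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2)
#' bits_from_image(m)
bits_from_image <- function(image) {
  if (is.character(image)) image <- read_bilevel(image)
  if (!is.matrix(image)) stop("image must be a matrix or a file path")
  v <- as.numeric(image)
  if (!all(v %in% c(0, 1))) stop("image is not bilevel (values must be 0/1)")
  bits <- as.integer(t(image))  # row-major
  attr(bits, "dim_image") <- dim(image)
  bits
}

#' Rebuild a bilevel image from bits
#'
#' Inverse of [bits_from_image()]: `image_from_bits(bits_from_image(x)) == x`.
#'
#' @param bits Integer 0/1 vector.
#' @param dim `c(rows, cols)`; defaults to the `dim_image` attribute.
#' @return 0/1 integer matrix (1 = black).
#' @export
image_from_bits <- function(bits, dim = attr(bits, "dim_image")) {
  if (is.null(dim)) stop("image dimensions missing")
  if (length(bits) != prod(dim)) stop("bit count does not match dimensions")
  matrix(as.integer(bits), nrow = dim[1], ncol = dim[2], byrow = TRUE)
}

read_bilevel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    g <- if (length(dim(a)) == 3L) a[, , 1L] else a
    if (!all(g %in% c(0, 1))) stop("PNG is not bilevel")
    matrix(as.integer(1 - g), nrow(g), ncol(g))  # PNG: 1 = white
  } else if (ext %in% c("pbm", "pnm")) {
    read_pbm(path)
  } else stop("unsupported image format: .", ext)
}

read_pbm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  toks <- scan(text = paste(txt, collapse = "\n"), what = character(),
               quiet = TRUE)
  if (toks[1] != "P1") stop("only ASCII PBM (P1) is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  bits <- as.integer(strsplit(paste(toks[-(1:3)], collapse = ""), "")[[1]])
  if (length(bits) != w * h || !all(bits %in% 0:1)) stop("malformed PBM")
  matrix(bits, nrow = h, ncol = w, byrow = TRUE)  # PBM: 1 = black
}

#' Write a bilevel image
#'
#' @param image 0/1 matrix (1 = black).
#' @param path Output path; `.png` or `.pbm` (ASCII P1).
#' @return `path`, invisibly.
#' @export
write_bilevel <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(1 - image, path)
  } else if (ext == "pbm") {
    rows <- apply(image, 1L, paste, collapse = " ")
    writeLines(c("P1", paste(ncol(image), nrow(image)), rows), path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Bits from a byte string
#'
#' Convenience for "0"/"1" strings with optional whitespace, e.g.
#' `"11001000 00010100"`.
#'
#' @param s Character scalar of 0s and 1s.
#' @return Integer bit vector.
#' @export
bits_from_string <- function(s) {
  b <- strsplit(gsub("[[:space:]]", "", s), "")[[1]]
  if (!all(b %in% c("0", "1"))) stop("not a binary string")
  as.integer(b)
}
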