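# Four-color DNA barcode rendering: one solid vertical bar per base
# (A green, T red, G black, C blue), a decoder for verification, and the
# FASTA-shaped QR payload text.

#' Four-color barcode palette
#'
#' A=green, T=red, G=black, C=blue; pure RGB primaries plus black by
#' default, overridable. Colors must be distinct.
#'
#' @param A,T,G,C Length-3 RGB vectors in \[0, 1\].
#' @export
barcode_palette <- function(A = c(0, 1, 0), T = c(1, 0, 0),
                            G = c(0, 0, 0), C = c(0, 0, 1)) {
  pal <- list(A = A, T = T, G = G, C = C)
  stopifnot(all(vapply(pal, length, 0L) == 3L),
            all(unlist(pal) >= 0), all(unlist(pal) <= 1))
  key <- vapply(pal, paste, "", collapse = ",")
  if (anyDuplicated(key)) stop("palette colors must be distinct", call. = FALSE)
  structure(pal, class = "barcode_palette")
}

#' Encode a sequence as a four-color barcode image
#'
#' One vertical bar per base, left to right in sequence order. Barcodes
#' encode resolved sequences only: `N` or gap characters are an error.
#'
#' @param sequence String over A/T/G/C.
#' @param palette A [barcode_palette()].
#' @param bar_width,bar_height Bar geometry in pixels.
#' @return A `barcode_image`: list with `pixels` (height x width x 3
#'   array), geometry and `sequence_length`.
#' @export
encode_barcode <- function(sequence, palette = barcode_palette(),
                           bar_width = 1L, bar_height = 50L) {
  stopifnot(bar_width >= 1L, bar_height >= 1L)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a nonempty string", call. = FALSE)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "T", "G", "C"))
  if (length(bad) > 0L)
    stop("barcode sequences must be fully resolved; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- length(chars)
  w <- n * bar_width
  px <- array(0, dim = c(bar_height, w, 3))
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * bar_width + 1L):(i * bar_width)
    rgbv <- palette[[chars[i]]]
    for (ch in 1:3) px[, cols, ch] <- rgbv[ch]
  }
  structure(list(pixels = px, bar_width = as.integer(bar_width),
                 bar_height = as.integer(bar_height), sequence_length = n),
            class = "barcode_image")
}

#' Decode a four-color barcode image back to its sequence
#'
#' Each bar must be a single solid color matching one palette entry
#' (nearest match within `tolerance` per channel); anything else —
#' including a single corrupted pixel — is a decode error naming the
#' offending pixel column.
#'
#' @param image A `barcode_image` (or a height x width x 3 pixel array
#'   plus `bar_width`).
#' @param palette A [barcode_palette()].
#' @param bar_width Required when `image` is a bare array.
#' @param tolerance Max per-channel deviation from a palette color.
#' @return The decoded sequence string.
#' @export
decode_barcode <- function(image, palette = barcode_palette(),
                           bar_width = NULL, tolerance = 0.2) {
  if (inherits(image, "barcode_image")) {
    px <- image$pixels
    bar_width <- image$bar_width
  } else {
    px <- image
    if (is.null(bar_width)) stop("bar_width required", call. = FALSE)
  }
  w <- dim(px)[2]
  if (w %% bar_width != 0L)
    stop("image width is not a multiple of bar_width", call. = FALSE)
  n <- w %/% bar_width
  out <- character(n)
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * bar_width + 1L):(i * bar_width)
    bar <- px[, cols, , drop = FALSE]
    first <- bar[1, 1, ]
    if (max(abs(sweep(bar, 3L, first))) > 1e-9)
      stop("decode error: bar ", i, " (pixel columns ", cols[1], "-",
           cols[length(cols)], ") is not a solid color", call. = FALSE)
    dev <- vapply(palette, function(p) max(abs(first - p)), 0)
    if (min(dev) > tolerance)
      stop("decode error: off-palette color at pixel column ", cols[1],
           call. = FALSE)
    out[i] <- names(palette)[which.min(dev)]
  }
  paste(out, collapse = "")
}

#' Write a barcode as SVG (the canonical, resolution-independent form)
#'
#' @param sequence String over A/T/G/C.
#' @param path Output path.
#' @param palette A [barcode_palette()].
#' @param bar_width,bar_height Bar geometry in SVG units.
#' @export
write_barcode_svg <- function(sequence, path, palette = barcode_palette(),
                              bar_width = 3, bar_height = 100) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c("A", "T", "G", "C"))
  if (length(bad) > 0L || length(chars) == 0L)
    stop("barcode sequences must be nonempty and fully resolved",
         call. = FALSE)
  hex <- vapply(palette, function(p)
    grDevices::rgb(p[1], p[2], p[3]), "")
  w <- length(chars) * bar_width
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    w, bar_height))
  for (i in seq_along(chars)) {
    lines <- c(lines, sprintf(
      '<rect x="%d" y="0" width="%d" height="%d" fill="%s"/>',
      (i - 1L) * bar_width, bar_width, bar_height, hex[[chars[i]]]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Write a barcode as PNG
#' @param image A `barcode_image`.
#' @param path Output path.
#' @export
write_barcode_png <- function(image, path) {
  stopifnot(inherits(image, "barcode_image"))
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' QR payload text for a marker sequence
#'
#' The payload the barcode/QR system encodes: a single FASTA entry whose
#' header carries accession, organism and gene separated by `|`. Stable
#' byte-wise, and parseable by [read_fasta()].
#'
#' @param accession,organism,gene Provenance strings (all required).
#' @param sequence Marker nucleotide sequence.
#' @return Payload text ending in a newline.
#' @export
make_qr_payload <- function(accession, organism, gene, sequence) {
  fields <- list(accession = accession, organism = organism, gene = gene,
                 sequence = sequence)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.character(v) || length(v) != 1L || !nzchar(v))
      stop("missing provenance field: ", nm, call. = FALSE)
  }
  sprintf(">%s|%s|%s\n%s\n", accession, organism, gene, sequence)
}
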