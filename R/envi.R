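# Minimal ENVI header + raw binary I/O for hyperspectral cubes and
# delimited-text I/O for single spectra.

#' Write a hyperspectral cube as ENVI header + binary
#'
#' Band-sequential (BSQ) float32 little-endian data in `<base>.dat` with a
#' standard ENVI text header `<base>.hdr` carrying the wavelength list.
#'
#' @param cube An [hscube()].
#' @param base Output path without extension.
#' @return The two file paths, invisibly.
#' @export
write_envi <- function(cube, base) {
  d <- dim(cube)
  w <- attr(cube, "wavelength")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = { ", paste(format(w, trim = TRUE), collapse = ", "), " }")
  )
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))                      # BSQ: each band row-major
    writeBin(as.numeric(t(cube[, , b])), con, size = 4, endian = "little")
  invisible(paste0(base, c(".hdr", ".dat")))
}

#' Read an ENVI cube written by [write_envi()]
#'
#' Supports BSQ and BIL interleaves of float32/float64 data.
#'
#' @param base Path without extension (expects `.hdr` and `.dat`).
#' @return An [hscube()].
#' @export
read_envi <- function(base) {
  hdr <- readLines(paste0(base, ".hdr"))
  field <- function(name) {
    ln <- grep(paste0("^", name, "\\s*="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(".*=", "", ln[1]))
  }
  samples <- as.integer(field("samples"))
  lines_n <- as.integer(field("lines"))
  bands <- as.integer(field("bands"))
  dtype <- as.integer(field("data type"))
  interleave <- tolower(field("interleave") %||% "bsq")
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  wline <- paste(hdr[grep("wavelength *= *\\{", hdr):length(hdr)], collapse = " ")
  wstr <- sub(".*\\{", "", sub("\\}.*", "", wline))
  w <- as.numeric(strsplit(wstr, ",")[[1]])
  raw <- readBin(paste0(base, ".dat"), "numeric", n = samples * lines_n * bands,
                 size = size, endian = "little")
  cube <- array(0, c(lines_n, samples, bands))
  if (interleave == "bsq") {
    for (b in seq_len(bands)) {
      off <- (b - 1L) * samples * lines_n
      cube[, , b] <- matrix(raw[off + seq_len(samples * lines_n)],
                            lines_n, samples, byrow = TRUE)
    }
  } else if (interleave == "bil") {
    idx <- 0L
    for (r in seq_len(lines_n)) for (b in seq_len(bands)) {
      cube[r, , b] <- raw[idx + seq_len(samples)]
      idx <- idx + samples
    }
  } else stop("unsupported interleave: ", interleave)
  hscube(cube, w)
}
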