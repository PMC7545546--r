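#' Minimal DICOM reader
#'
#' Reads the subset of DICOM needed to import a radiograph for landmark
#' annotation: uncompressed, explicit-VR little-endian files (transfer
#' syntax 1.2.840.10008.1.2.1) with monochrome 8- or 16-bit pixel data.
#' Extracts Rows, Columns, BitsAllocated, PixelSpacing and PixelData.
#' Files using other transfer syntaxes (implicit VR, compressed) are
#' rejected with an error.
#'
#' @param path DICOM file path.
#' @return list with \code{pixels} (integer matrix, rows = image rows),
#'   \code{spacing} (length-2 numeric, mm per pixel, row then column;
#'   \code{c(1, 1)} with unit "px" and a warning when PixelSpacing is
#'   absent), \code{unit}, and \code{source = "dicom"}.
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132 + 8 ||
      rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic) or file truncated",
         call. = FALSE)
  pos <- 133L                      # 1-based offset past preamble + magic
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  transfer_syntax <- NULL
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (expected explicit VR little endian)",
           call. = FALSE)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    start <- pos + hdr
    if (start + len - 1L > length(raw))
      stop("truncated DICOM element", call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0002,0010", "0028,0010", "0028,0011", "0028,0100",
                   "0028,0030", "7fe0,0010")) {
      elems[[key]] <- raw[start:(start + len - 1L)]
    }
    pos <- start + len
    if (key == "7fe0,0010") break
  }
  ts <- elems[["0002,0010"]]
  if (!is.null(ts)) {
    ts <- ts[ts != as.raw(0)]                 # strip NUL padding
    transfer_syntax <- sub("\\s+$", "", rawToChar(ts))
    if (transfer_syntax != "1.2.840.10008.1.2.1")
      stop(sprintf("unsupported DICOM transfer syntax '%s'", transfer_syntax),
           call. = FALSE)
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  miss <- setdiff(need, names(elems))
  if (length(miss))
    stop(sprintf("DICOM missing required element(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  rows <- u16_val(elems[["0028,0010"]])
  cols <- u16_val(elems[["0028,0011"]])
  bits <- if (!is.null(elems[["0028,0100"]])) u16_val(elems[["0028,0100"]])
          else 16L
  pd <- elems[["7fe0,0010"]]
  px <- if (bits <= 8) {
    as.integer(pd)
  } else {
    readBin(pd, "integer", n = length(pd) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")
  }
  if (length(px) < rows * cols)
    stop("truncated DICOM pixel data", call. = FALSE)
  pixels <- matrix(px[seq_len(rows * cols)], nrow = rows, byrow = TRUE)
  sp <- elems[["0028,0030"]]
  if (is.null(sp)) {
    warning("DICOM has no PixelSpacing; using 1 px", call. = FALSE)
    spacing <- c(1, 1); unit <- "px"
  } else {
    spacing <- as.numeric(strsplit(rawToChar(sp), "\\\\")[[1]])
    unit <- "mm"
  }
  list(pixels = pixels, spacing = spacing, unit = unit, source = "dicom")
}

u16_val <- function(r) as.integer(r[1]) + 256L * as.integer(r[2])
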