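## writes a tiny synthetic DICOM file (explicit VR little endian) at test
## time; binary fixtures are never stored in the repository.
write_minimal_dicom <- function(path, pixels = matrix(0:15, 4, 4, byrow = TRUE),
                                spacing = c(0.2, 0.2),
                                with_spacing = TRUE) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  elem_short <- function(group, el, vr, payload) {
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(length(payload)); writeBin(payload, con)
  }
  elem_long <- function(group, el, vr, payload) {
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(0); u32(length(payload)); writeBin(payload, con)
  }
  str_pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  }
  u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
  elem_short(0x0002, 0x0010, "UI", str_pad("1.2.840.10008.1.2.1"))
  elem_short(0x0028, 0x0010, "US", u16raw(nrow(pixels)))
  elem_short(0x0028, 0x0011, "US", u16raw(ncol(pixels)))
  elem_short(0x0028, 0x0100, "US", u16raw(16L))
  if (with_spacing)
    elem_short(0x0028, 0x0030, "DS",
               str_pad(paste(sprintf("%g", spacing), collapse = "\\")))
  px <- as.integer(t(pixels))                 # row-major pixel order
  pd <- writeBin(px, raw(), size = 2, endian = "little")
  elem_long(0x7fe0, 0x0010, "OW", pd)
  invisible(path)
}
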