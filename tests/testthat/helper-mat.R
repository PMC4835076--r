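# Minimal MAT v5 writer used only to build test fixtures for the reader.
# Supports double vectors/matrices, character vectors (char matrices) and
# one level of named-list -> struct. Uncompressed, little-endian.

mat_raw <- function(writer) {
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  writer(con)
  rawConnectionValue(con)
}

mat_pad8 <- function(b) c(b, raw((8L - length(b) %% 8L) %% 8L))

mat_element <- function(type, payload) {
  hdr <- mat_raw(function(con) {
    writeBin(as.integer(type), con, size = 4L, endian = "little")
    writeBin(length(payload), con, size = 4L, endian = "little")
  })
  c(hdr, mat_pad8(payload))
}

mat_matrix_element <- function(name, value) {
  body <- if (is.numeric(value)) {
    dm <- if (is.matrix(value)) dim(value) else c(length(value), 1L)
    c(mat_element(6L, mat_raw(function(con)      # array flags: mxDOUBLE
        writeBin(c(6L, 0L), con, size = 4L, endian = "little"))),
      mat_element(5L, mat_raw(function(con)
        writeBin(as.integer(dm), con, size = 4L, endian = "little"))),
      mat_element(1L, charToRaw(name)),
      mat_element(9L, mat_raw(function(con)
        writeBin(as.numeric(value), con, size = 8L, endian = "little"))))
  } else if (is.character(value)) {
    wd <- max(nchar(value))
    padded <- formatC(value, width = -wd)           # right-pad with spaces
    codes <- unlist(lapply(padded, utf8ToInt))
    m <- matrix(codes, nrow = length(value), byrow = TRUE)
    c(mat_element(6L, mat_raw(function(con)
        writeBin(c(4L, 0L), con, size = 4L, endian = "little"))),  # mxCHAR
      mat_element(5L, mat_raw(function(con)
        writeBin(c(length(value), wd), con, size = 4L, endian = "little"))),
      mat_element(1L, charToRaw(name)),
      mat_element(4L, mat_raw(function(con)        # miUINT16, column-major
        writeBin(as.integer(as.vector(m)), con, size = 2L, endian = "little"))))
  } else if (is.list(value)) {
    fnames <- names(value)
    flen <- 32L
    namebytes <- unlist(lapply(fnames, function(f) {
      b <- charToRaw(f); c(b, raw(flen - length(b)))
    }))
    fields <- unlist(lapply(fnames, function(f)
      mat_matrix_element("", value[[f]])))
    c(mat_element(6L, mat_raw(function(con)
        writeBin(c(2L, 0L), con, size = 4L, endian = "little"))),  # mxSTRUCT
      mat_element(5L, mat_raw(function(con)
        writeBin(c(1L, 1L), con, size = 4L, endian = "little"))),
      mat_element(1L, charToRaw(name)),
      mat_element(5L, mat_raw(function(con)        # field name length
        writeBin(flen, con, size = 4L, endian = "little"))),
      mat_element(1L, namebytes),
      fields)
  } else stop("unsupported fixture type")
  mat_element(14L, body)
}

write_mat_fixture <- function(path, vars) {
  header <- charToRaw(sprintf("%-116s", "MATLAB 5.0 MAT-file, test fixture"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(raw(8L), con)                            # subsys offset
  writeBin(c(as.raw(0L), as.raw(1L)), con)          # version 0x0100 LE
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) writeBin(mat_matrix_element(nm, vars[[nm]]), con)
  invisible(path)
}
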