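# Minimal MAT-file (level 5, uncompressed) reader. Supports numeric arrays
# (stored as any integer/double type), char arrays, structs and cells, which
# covers clinical/demographic tables in a deposited MAT dataset. Compressed
# (miCOMPRESSED) elements and v7.3/HDF5 files raise a clear error.

MI_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
              `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_data <- function(raw, pos, type, nbytes, endian) {
  n <- if (type %in% c(1L, 2L)) nbytes else nbytes / MI_SIZES[[as.character(type)]]
  bytes <- raw[pos:(pos + nbytes - 1L)]
  switch(as.character(type),
    "1" = readBin(bytes, integer(), n, size = 1L, signed = TRUE),
    "2" = readBin(bytes, integer(), n, size = 1L, signed = FALSE),
    "3" = readBin(bytes, integer(), n, size = 2L, signed = TRUE, endian = endian),
    "4" = readBin(bytes, integer(), n, size = 2L, signed = FALSE, endian = endian),
    "5" = readBin(bytes, integer(), n, size = 4L, endian = endian),
    "6" = as.numeric(readBin(bytes, integer(), n, size = 4L, endian = endian)),
    "7" = readBin(bytes, numeric(), n, size = 4L, endian = endian),
    "9" = readBin(bytes, numeric(), n, size = 8L, endian = endian),
    stop("unsupported MAT data type code ", type))
}

# parse one tagged element starting at pos; returns list(type, data_raw
# bounds, next position). Small-element format packs <=4 byte payloads.
mat_tag <- function(raw, pos, endian) {
  t32 <- readBin(raw[pos:(pos + 3L)], integer(), 1L, size = 4L, endian = endian)
  small <- bitwAnd(t32, -65536L)  # upper 16 bits nonzero -> small element
  if (small != 0L) {
    type <- bitwAnd(t32, 65535L)
    nbytes <- bitwShiftR(bitwAnd(t32, -65536L), 16L)
    list(type = type, nbytes = nbytes, data_pos = pos + 4L, next_pos = pos + 8L)
  } else {
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], integer(), 1L, size = 4L,
                      endian = endian)
    padded <- nbytes + (8L - nbytes %% 8L) %% 8L
    list(type = t32, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + 8L + padded)
  }
}

parse_matrix <- function(raw, pos, endian) {
  # array flags
  tg <- mat_tag(raw, pos, endian)
  flags <- readBin(raw[tg$data_pos:(tg$data_pos + 7L)], integer(), 2L,
                   size = 4L, endian = endian)
  cls <- bitwAnd(flags[1L], 255L)
  pos <- tg$next_pos
  # dimensions
  tg <- mat_tag(raw, pos, endian)
  dims <- read_mi_data(raw, tg$data_pos, tg$type, tg$nbytes, endian)
  pos <- tg$next_pos
  # name
  tg <- mat_tag(raw, pos, endian)
  name <- if (tg$nbytes > 0L)
    rawToChar(raw[tg$data_pos:(tg$data_pos + tg$nbytes - 1L)]) else ""
  pos <- tg$next_pos

  if (cls %in% c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L)) {  # numeric
    tg <- mat_tag(raw, pos, endian)
    vals <- if (tg$nbytes > 0L)
      read_mi_data(raw, tg$data_pos, tg$type, tg$nbytes, endian) else numeric(0)
    pos <- tg$next_pos
    val <- if (length(dims) == 2L && any(dims == 1L)) as.numeric(vals)
           else array(as.numeric(vals), dim = dims)
  } else if (cls == 4L) {                                          # char
    tg <- mat_tag(raw, pos, endian)
    codes <- if (tg$nbytes > 0L)
      read_mi_data(raw, tg$data_pos, tg$type, tg$nbytes, endian) else integer(0)
    pos <- tg$next_pos
    if (length(dims) == 2L && dims[1L] > 1L) {
      m <- matrix(codes, dims[1L], dims[2L])
      val <- apply(m, 1L, function(rw) trimws(intToUtf8(rw)))
    } else {
      val <- intToUtf8(codes)
    }
  } else if (cls == 2L) {                                          # struct
    tg <- mat_tag(raw, pos, endian)    # field name length (int32)
    flen <- read_mi_data(raw, tg$data_pos, tg$type, tg$nbytes, endian)[1L]
    pos <- tg$next_pos
    tg <- mat_tag(raw, pos, endian)    # field names
    nf <- tg$nbytes / flen
    fnames <- vapply(seq_len(nf), function(k) {
      b <- raw[(tg$data_pos + (k - 1L) * flen):(tg$data_pos + k * flen - 1L)]
      rawToChar(b[b != as.raw(0L)])
    }, character(1L))
    pos <- tg$next_pos
    nel <- prod(dims)
    fields <- vector("list", nf * nel)
    for (k in seq_len(nf * nel)) {
      tg <- mat_tag(raw, pos, endian)
      if (tg$type != 14L) stop("malformed struct field in MAT file")
      sub <- parse_matrix(raw, tg$data_pos, endian)
      fields[[k]] <- sub$value
      pos <- tg$next_pos
    }
    if (nel == 1L) {
      val <- setNames(fields, fnames)
    } else {  # struct array: list of structs
      val <- lapply(seq_len(nel), function(e)
        setNames(fields[((e - 1L) * nf + 1L):(e * nf)], fnames))
    }
  } else if (cls == 1L) {                                          # cell
    nel <- prod(dims)
    val <- vector("list", nel)
    for (k in seq_len(nel)) {
      tg <- mat_tag(raw, pos, endian)
      if (tg$type != 14L) stop("malformed cell element in MAT file")
      sub <- parse_matrix(raw, tg$data_pos, endian)
      val[[k]] <- sub$value
      pos <- tg$next_pos
    }
  } else {
    stop("unsupported MAT array class ", cls)
  }
  list(name = name, value = val)
}

#' Read an uncompressed MAT (level 5) file
#'
#' @param path MAT file.
#' @return Named list of top-level variables.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("MAT file not found: ", path)
  raw <- readBin(path, raw(), file.size(path))
  if (length(raw) < 128L) stop("not a MAT v5 file (too short): ", path)
  if (identical(raw[1:4], charToRaw("\x89HDF")) ||
      identical(raw[2:4], charToRaw("HDF")))
    stop("MAT v7.3 (HDF5) files are not supported by this reader")
  endmark <- rawToChar(raw[127:128])
  endian <- if (endmark == "IM") "little" else if (endmark == "MI") "big"
            else stop("not a MAT v5 file: ", path)
  pos <- 129L
  out <- list()
  while (pos + 8L <= length(raw)) {
    tg <- mat_tag(raw, pos, endian)
    if (tg$type == 15L)
      stop("compressed MAT elements are not supported; re-save with '-v6'")
    if (tg$type != 14L) stop("unexpected top-level MAT element type ", tg$type)
    el <- parse_matrix(raw, tg$data_pos, endian)
    out[[el$name]] <- el$value
    pos <- tg$next_pos
  }
  out
}

# clinical field aliases for schema discovery (lower-cased, non-alnum removed)
S1_FIELD_ALIASES <- list(
  id = c("id", "subject", "subjectid", "code"),
  group = c("group", "diagnosis", "status"),
  age = c("age", "ageyears"),
  sex = c("sex", "gender"),
  disease_duration_years = c("diseaseduration", "duration", "durationyears",
                             "diseasedurationyears"),
  mmt_c5 = c("mmtc5", "c5"), mmt_c6 = c("mmtc6", "c6"),
  mmt_c7 = c("mmtc7", "c7"), mmt_c8 = c("mmtc8", "c8"),
  mmt_arm = c("mmtarm", "arm"), mmt_leg = c("mmtleg", "leg"),
  mmt_total = c("mmttotal", "totalmmt"),
  mfm_d1 = c("mfmd1", "d1"), mfm_d2 = c("mfmd2", "d2"), mfm_d3 = c("mfmd3", "d3"),
  alsfrs_arm = c("alsfrsarm", "alsfrsrarm"),
  alsfrs_leg = c("alsfrsleg", "alsfrsrleg"),
  alsfrs_total = c("alsfrstotal", "alsfrsrtotal", "alsfrs"))

canon_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Load the deposited cohort MAT dataset
#'
#' Schema-discovering loader for the supplementary cohort MAT-file
#' (individual MRI measurements, demographics and clinical features). Known
#' clinical fields are mapped onto the `SubjectRecord` schema by name
#' matching; everything unrecognized (for example per-subject measurement
#' arrays) is preserved untouched in `$raw`. MMT percent-of-maximum columns
#' are derived from raw subscores when absent.
#'
#' @param path MAT file path.
#' @param quiet suppress the schema report.
#' @return List with `records` (data frame), `raw` (unmapped variables) and
#'   `schema` (mapping report).
#' @export
load_s1_dataset <- function(path, quiet = FALSE) {
  if (!file.exists(path))
    stop("cohort dataset not found at '", path,
         "': expected the supplementary MAT-file with individual MRI data, ",
         "demographics and clinical features")
  vars <- read_mat(path)
  # locate a struct of per-subject vectors: either top-level fields or one
  # struct variable holding them
  fields <- vars
  for (v in vars) {
    if (is.list(v) && !is.null(names(v)) && length(names(v)) > 3L) {
      fields <- v
      break
    }
  }
  canon <- canon_name(names(fields))
  mapped <- list(); used <- character(0)
  for (tgt in names(S1_FIELD_ALIASES)) {
    hit <- which(canon %in% S1_FIELD_ALIASES[[tgt]])
    if (length(hit) > 0L) {
      val <- fields[[hit[1L]]]
      mapped[[tgt]] <- if (is.list(val)) unlist(val) else as.vector(val)
      used <- c(used, names(fields)[hit[1L]])
    }
  }
  if (length(mapped) == 0L)
    stop("no recognizable clinical fields in ", path)
  n <- max(lengths(mapped))
  mapped <- lapply(mapped, function(v) { length(v) <- n; v })
  records <- as.data.frame(mapped, stringsAsFactors = FALSE)
  if (!is.null(records$group)) {
    g <- tolower(as.character(records$group))
    records$group <- ifelse(grepl("^(p|sma|1)", g), "patient", "control")
  }
  maxima <- c(mmt_c5 = 10, mmt_c6 = 10, mmt_c7 = 30, mmt_c8 = 20)
  for (f in names(maxima)) {
    pf <- sub("mmt_", "mmt_pct_", f)
    if (!pf %in% names(records) && f %in% names(records))
      records[[pf]] <- 100 * as.numeric(records[[f]]) / maxima[[f]]
  }
  raw <- fields[setdiff(names(fields), used)]
  schema <- data.frame(mat_field = names(fields),
                       mapped_to = vapply(names(fields), function(nm) {
                         i <- which(vapply(names(S1_FIELD_ALIASES), function(t)
                           canon_name(nm) %in% S1_FIELD_ALIASES[[t]], logical(1L)))
                         if (length(i) > 0L) names(S1_FIELD_ALIASES)[i[1L]] else "(raw)"
                       }, character(1L)))
  miss <- setdiff(names(S1_FIELD_ALIASES), names(records))
  if (length(miss) > 0L)
    warning("clinical fields missing from dataset (set to NA): ",
            paste(miss, collapse = ", "))
  for (f in miss) records[[f]] <- NA
  if (!quiet) {
    message(sprintf("loaded %d subject records (%s)", nrow(records),
                    paste(capture_groups(records$group), collapse = ", ")))
    message("schema: ", paste(schema$mat_field, "->", schema$mapped_to,
                              collapse = "; "))
  }
  list(records = records, raw = raw, schema = schema)
}

capture_groups <- function(g) {
  if (all(is.na(g))) return("group unknown")
  tb <- table(g)
  paste0(tb, " ", names(tb))
}
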