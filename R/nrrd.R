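# Minimal NRRD (NRRD0004) reader/writer for 3-D scalar volumes.
# Supports raw and gzip encodings, little-endian, the numeric types this
# package emits. No installed package provides NRRD I/O, so the format is
# handled directly; the header subset follows the NRRD specification.

nrrd_type_map <- c(
  "unsigned char" = "uint8", "uint8" = "uint8", "uchar" = "uint8",
  "short" = "int16", "int16" = "int16", "signed short" = "int16",
  "unsigned short" = "uint16", "uint16" = "uint16", "ushort" = "uint16",
  "int" = "int32", "int32" = "int32", "signed int" = "int32",
  "unsigned int" = "uint32", "uint32" = "uint32",
  "float" = "float", "double" = "double")

read_nrrd_raw <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-9]$", magic)) stopf("format error: not an NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stopf("format error: truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) != 2) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  type <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(type)) stopf("format error: unsupported NRRD type '%s'",
                           fields[["type"]])
  ndim <- as.integer(fields[["dimension"]])
  if (ndim != 3) stopf("format error: expected a 3-D NRRD (dimension %d)", ndim)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")

  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- sapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
    spacing <- sqrt(colSums(m^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])

  n <- prod(sizes)
  size_of <- c(uint8 = 1L, int16 = 2L, uint16 = 2L, int32 = 4L,
               uint32 = 4L, float = 4L, double = 8L)[[type]]
  payload <- readBin(con, "raw", n = file.size(path))
  if (encoding == "gzip" || encoding == "gz") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stopf("format error: unsupported NRRD encoding '%s'", encoding)
  }
  what <- if (type %in% c("float", "double")) "double" else "integer"
  signed <- !(type %in% c("uint8", "uint16", "uint32"))
  vals <- readBin(payload, what, n = n, size = size_of, signed = signed,
                  endian = endian)
  if (length(vals) != n) stopf("format error: NRRD payload too short")
  list(values = array(as.numeric(vals), dim = sizes), spacing = spacing,
       origin = origin, type = type)
}

#' Write a volume as NRRD
#'
#' Serializes a [density_volume], [signed_distance_volume], or plain
#' numeric/integer 3-D array (with explicit geometry) as a little-endian
#' raw-encoded NRRD0004 file.
#'
#' @param x the volume to write.
#' @param path output file path.
#' @param type storage type: `"double"`, `"float"`, `"uint16"`, or
#'   `"uint8"`.
#' @param spacing_mm,origin_mm grid geometry, required when `x` is a bare
#'   array.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, type = "double", spacing_mm = NULL,
                       origin_mm = NULL) {
  if (is_density_volume(x)) {
    vals <- x$values; spacing_mm <- x$spacing_mm; origin_mm <- x$origin_mm
  } else if (is_sdf(x)) {
    vals <- x$distances; spacing_mm <- x$spacing_mm; origin_mm <- x$origin_mm
  } else {
    vals <- x
    if (is.null(spacing_mm)) stopf("spacing_mm required for bare arrays")
    origin_mm <- origin_mm %||% c(0, 0, 0)
  }
  dims <- dim(vals)
  nrrd_type <- c(double = "double", float = "float",
                 uint16 = "unsigned short", uint8 = "unsigned char")[[type]]
  if (is.null(nrrd_type)) stopf("unsupported write type '%s'", type)
  con <- file(path, "wb")
  on.exit(close(con))
  dirs <- sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                  spacing_mm[1], spacing_mm[2], spacing_mm[3])
  header <- c(
    "NRRD0004",
    paste0("type: ", nrrd_type),
    "dimension: 3",
    "space dimension: 3",
    paste0("sizes: ", paste(dims, collapse = " ")),
    paste0("space directions: ", dirs),
    "kinds: domain domain domain",
    "encoding: raw",
    "endian: little",
    sprintf("space origin: (%.17g,%.17g,%.17g)", origin_mm[1],
            origin_mm[2], origin_mm[3]),
    "")
  writeLines(header, con, sep = "\n")
  v <- as.vector(vals)
  size <- switch(type, double = 8L, float = 4L, uint16 = 2L, uint8 = 1L)
  if (type %in% c("uint16", "uint8")) v <- as.integer(round(v))
  writeBin(v, con, size = size, endian = "little")
  invisible(path)
}
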