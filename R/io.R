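# Volume and table I/O. Open formats only: NRRD (native reader/writer,
# text header + raw or gzip block), NIfTI-1 (via RNifti), multi-page TIFF
# (via the tiff package), CSV/XLSX specimen tables. Arrays are normalized to
# the package's (z, y, x) axis order; label volumes are recognised by
# integer storage plus an optional JSON sidecar label map.

nrrd_types <- list(
  "float" = list(what = "numeric", size = 4),
  "double" = list(what = "numeric", size = 8),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE)
)

#' Write a volume as NRRD
#'
#' Images are stored as little-endian float32, label volumes as uint8 with
#' the label map in a `<path>.labels.json` sidecar; the isotropic spacing
#' goes into the `spacings` header field.
#'
#' @param v a [volume3d()] or [label_volume()].
#' @param path output path (conventionally `.nrrd`).
#' @param encoding `"raw"` or `"gzip"`.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(v, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  is_lab <- inherits(v, "label_volume")
  arr <- as_vol_array(v)
  d <- dim(arr)
  sp <- if (is_lab || inherits(v, "volume3d")) v$spacing_mm else 1
  type <- if (is_lab) "uint8" else "float"
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("spacings: ", paste(rep(sp, 3), collapse = " ")),
           paste0("encoding: ", encoding),
           "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- if (is_lab) writeBin_raw(as.integer(arr), 1L)
             else writeBin_raw(as.numeric(arr), 4L)
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  writeBin(payload, con)
  if (is_lab)
    jsonlite::write_json(v$labels, paste0(path, ".labels.json"),
                         dataframe = "rows")
  invisible(path)
}

writeBin_raw <- function(x, size) {
  if (size == 1) as.raw(x)
  else writeBin(x, raw(), size = size, endian = "little")
}

#' Read an NRRD volume
#'
#' @param path NRRD file path.
#' @return a [volume3d()] (float types) or [label_volume()] (integer types;
#'   the label map is taken from the `<path>.labels.json` sidecar when
#'   present, otherwise from the values found).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD"))
    stop("read_nrrd: not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop("read_nrrd: truncated header in ", path)
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[tolower(kv[1])] <- kv[2]
  }
  type <- tolower(fields$type %||% "float")
  tinfo <- nrrd_types[[type]]
  if (is.null(tinfo)) stop("read_nrrd: unsupported type '", type, "'")
  d <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(d) != 3) stop("read_nrrd: only 3-dimensional volumes supported")
  n <- prod(d)
  enc <- tolower(fields$encoding %||% "raw")
  payload <- readBin(con, raw(), n = file.size(path))
  if (enc == "gzip") payload <- memDecompress(payload, "gzip")
  else if (enc != "raw") stop("read_nrrd: unsupported encoding '", enc, "'")
  if (length(payload) < n * tinfo$size)
    stop("read_nrrd: truncated data block in ", path)
  vals <- if (tinfo$size == 1) as.integer(payload[seq_len(n)])
          else readBin(payload, tinfo$what, n = n, size = tinfo$size,
                       signed = tinfo$signed %||% TRUE, endian = "little")
  spacing <- if (!is.null(fields$spacings)) {
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]])[1]
  } else {
    warning("read_nrrd: no spacing in header; defaulting to 1 mm")
    1
  }
  arr <- array(vals, d)
  if (tinfo$what == "integer") {
    side <- paste0(path, ".labels.json")
    labs <- if (file.exists(side)) {
      as.data.frame(jsonlite::read_json(side, simplifyVector = TRUE))
    } else {
      ids <- sort(setdiff(unique(vals), 0L))
      if (setequal(ids, 1:6) || all(ids %in% 1:6)) neuropil_labels()
      else data.frame(id = ids, name = paste0("L", ids), paired = FALSE)
    }
    label_volume(arr, labs, spacing)
  } else {
    volume3d(arr, spacing)
  }
}

#' Read a 3D volume (NRRD, NIfTI-1 or multi-page TIFF)
#'
#' Axis order is normalized to (z, y, x). Integer-typed data yields a
#' [label_volume()], float data a [volume3d()]. A missing voxel spacing
#' (always the case for plain TIFF) falls back to 1 mm with a warning.
#'
#' @param path input file.
#' @return [volume3d()] or [label_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return(read_nrrd(path))
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1]
    arr <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
    if (!is.na(sp) && sp > 0) volume3d(arr, sp)
    else {
      warning("read_volume: no spacing in NIfTI header; defaulting to 1 mm")
      volume3d(arr, 1)
    }
  } else if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    arr <- aperm(simplify2array(pages), c(3, 1, 2))  # pages -> z
    warning("read_volume: TIFF carries no spacing metadata; defaulting to 1 mm")
    if (is.integer(arr) && max(arr) <= 6) label_volume(arr, spacing_mm = 1)
    else volume3d(arr * 1.0, 1)
  } else stop("read_volume: unsupported format: ", path)
}

#' Write a 3D volume (format chosen by extension)
#'
#' @param v [volume3d()] or [label_volume()].
#' @param path output path ending in `.nrrd`, `.nii`/`.nii.gz` or `.tif(f)`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return(write_nrrd(v, path))
  arr <- as_vol_array(v)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    out <- aperm(arr, c(3, 2, 1))
    img <- RNifti::asNifti(out)
    RNifti::pixdim(img) <- rep(v$spacing_mm, 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", lower)) {
    sc <- max(abs(arr), 1e-12)
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / sc)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else stop("write_volume: unsupported format: ", path)
  invisible(path)
}

# column synonyms accepted in external specimen tables
specimen_column_synonyms <- function() {
  syn <- utils::read.csv(system.file("extdata", "specimen_column_synonyms.csv",
                                     package = "hivemorph"),
                         stringsAsFactors = FALSE)
  split(syn$synonym, syn$canonical)
}

#' Read a per-specimen volume table (CSV or XLSX)
#'
#' Accepts the package's own CSV layout as well as tables using documented
#' column synonyms (e.g. `Total brain volume` for `total`). Rows with
#' missing left or right mushroom-body volumes are marked non-separable.
#' Rows whose OL deviates from ME + LO by more than `tol` (relative) draw a
#' consistency warning.
#'
#' @param path CSV or XLSX file.
#' @param tol relative tolerance of the OL = ME + LO consistency check.
#' @return a `specimen_table` data.frame.
#' @export
read_specimen_table <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stop("read_specimen_table: file not found: ", path)
  if (grepl("\\.xlsx$", tolower(path))) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("read_specimen_table: reading XLSX requires the readxl package")
    t <- as.data.frame(readxl::read_excel(path))
  } else {
    t <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
      error = function(e)
        stop("read_specimen_table: empty or unreadable table in ", path))
  }
  if (nrow(t) == 0 || ncol(t) == 0)
    stop("read_specimen_table: empty table in ", path)
  syn <- specimen_column_synonyms()
  for (canon in names(syn)) {
    if (canon %in% names(t)) next
    hit <- intersect(syn[[canon]], names(t))
    if (length(hit)) names(t)[names(t) == hit[1]] <- canon
  }
  mandatory <- c("AL", "MB", "CX", "ME", "LO", "OTH")
  missing_cols <- setdiff(mandatory, names(t))
  if (length(missing_cols))
    stop("read_specimen_table: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"OL" %in% names(t)) t$OL <- t$ME + t$LO
  if (!"total" %in% names(t))
    t$total <- t$AL + t$MB + t$CX + t$ME + t$LO + t$OTH
  bad <- which(abs(t$OL - (t$ME + t$LO)) > tol * pmax(t$OL, 1e-12))
  if (length(bad))
    warning("read_specimen_table: OL != ME + LO beyond tolerance in row(s) ",
            paste(bad, collapse = ", "))
  if (all(c("MB_left", "MB_right") %in% names(t)))
    t$mb_separable <- !is.na(t$MB_left) & !is.na(t$MB_right)
  else if (!"mb_separable" %in% names(t)) t$mb_separable <- NA
  class(t) <- c("specimen_table", class(t))
  t
}
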