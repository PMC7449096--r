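#' Read a 3D volume from an open file format
#'
#' Supported formats: NRRD (`.nrrd`, raw encoding), MetaImage (`.mhd` header +
#' `.raw` data) and multi-page TIFF stacks (`.tif`/`.tiff`, one axial slice
#' per page, integer greyscale). The grid is returned in the package's
#' canonical layout (`data[x, y, z]`, x fastest; see [volume3d()]).
#'
#' The voxel size must be isotropic. For NRRD and MetaImage it is taken from
#' the header (`spacings`/`ElementSpacing`); anisotropic spacing is rejected
#' rather than resampled, since silent resampling would corrupt downstream
#' measurements. TIFF carries no spacing metadata, so `voxel_size_mm` is
#' mandatory for TIFF input; there is never a silent default.
#'
#' @param path path to a `.nrrd`, `.mhd` or `.tif`/`.tiff` file.
#' @param voxel_size_mm isotropic voxel size in mm; optional when the file
#'   metadata provides it (it is then checked for consistency if given).
#' @return A [volume3d()] object.
#' @seealso [write_volume()], [as_label_map()]
#' @export
read_volume <- function(path, voxel_size_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  res <- switch(ext,
    nrrd = read_nrrd(path),
    mhd  = read_mhd(path),
    tif  = ,
    tiff = read_tiff_stack(path),
    stop("unsupported volume format '.", ext, "' for ", path,
         " (supported: .nrrd, .mhd, .tif/.tiff)")
  )
  vs <- res$voxel_size_mm
  if (is.null(vs)) {
    if (is.null(voxel_size_mm))
      stop("no voxel size in ", path,
           " metadata and none supplied; pass voxel_size_mm explicitly")
    vs <- voxel_size_mm
  } else if (!is.null(voxel_size_mm) &&
             abs(vs - voxel_size_mm) > 1e-9 * vs) {
    stop("voxel_size_mm = ", voxel_size_mm, " contradicts ", path,
         " metadata spacing ", vs)
  }
  volume3d(res$data, vs)
}

#' Write a 3D volume or label map
#'
#' Writes [volume3d()], [binary_mask()], [label_map()] or [part_label_map()]
#' objects. Integer-valued grids (labels, masks) are stored with an integer
#' element type so they round-trip exactly; greyscale volumes are stored as
#' 64-bit floats in NRRD/MetaImage. TIFF output is restricted to non-negative
#' integer-valued data up to 16 bits (the `tiff` package clamps floats to
#' \[0, 1\]); use NRRD or MetaImage for float volumes.
#'
#' @param vol a grid object to write.
#' @param path output path; the extension selects the format. For `.mhd` a
#'   sibling `.raw` file is written.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, c("nut_volume", "nut_mask", "nut_labels", "nut_parts")))
    stop("vol must be a nut_volume / nut_mask / nut_labels / nut_parts object")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write ", path, ": directory ", dir,
                             " does not exist")
  data <- vol$data
  integral <- is.integer(data) || is.logical(data)
  if (integral) storage.mode(data) <- "integer"
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = write_nrrd(data, vol$voxel_size_mm, path, integral),
    mhd  = write_mhd(data, vol$voxel_size_mm, path, integral),
    tif  = ,
    tiff = write_tiff_stack(data, path),
    stop("unsupported volume format '.", ext, "' for ", path)
  )
  invisible(path)
}

#' Reinterpret an integer-valued volume as a label map
#'
#' Convenience for round-tripping label maps through [read_volume()].
#'
#' @param vol a [volume3d()] with non-negative integer-valued data.
#' @return A [label_map()].
#' @export
as_label_map <- function(vol) {
  d <- vol$data
  if (max(abs(d - round(d))) > 0) stop("volume is not integer-valued")
  label_map(array(as.integer(round(d)), dim(d)), vol$voxel_size_mm)
}

# ---- NRRD (raw encoding) ----------------------------------------------------

nrrd_types <- list(
  "double" = list(size = 8, what = "double", signed = TRUE),
  "float"  = list(size = 4, what = "double", signed = TRUE),
  "int"    = list(size = 4, what = "integer", signed = TRUE),
  "int32"  = list(size = 4, what = "integer", signed = TRUE),
  "short"  = list(size = 2, what = "integer", signed = TRUE),
  "int16"  = list(size = 2, what = "integer", signed = TRUE),
  "ushort" = list(size = 2, what = "integer", signed = FALSE),
  "uint16" = list(size = 2, what = "integer", signed = FALSE),
  "uchar"  = list(size = 1, what = "integer", signed = FALSE),
  "uint8"  = list(size = 1, what = "integer", signed = FALSE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop(path, " is not a NRRD file")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (is.null(fields$dimension) || as.integer(fields$dimension) != 3L)
    stop(path, ": only 3-dimensional NRRD volumes are supported")
  enc <- tolower(fields$encoding %||% "raw")
  if (enc != "raw") stop(path, ": only raw NRRD encoding is supported, got ", enc)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- tolower(fields$type %||% "double")
  ti <- nrrd_types[[type]]
  if (is.null(ti)) stop(path, ": unsupported NRRD type ", type)
  endian <- if (identical(tolower(fields$endian %||% "little"), "big"))
    "big" else "little"
  n <- prod(sizes)
  raw <- readBin(con, what = ti$what, n = n, size = ti$size,
                 signed = ti$signed, endian = endian)
  if (length(raw) != n) stop(path, ": truncated NRRD data")
  vs <- NULL
  if (!is.null(fields$spacings)) {
    sp <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
    vs <- isotropic_spacing(sp, path)
  } else if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    sp <- vapply(dirs, function(s) {
      v <- as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
    vs <- isotropic_spacing(sp, path)
  }
  list(data = array(raw, sizes), voxel_size_mm = vs)
}

write_nrrd <- function(data, voxel_size_mm, path, integral) {
  type <- if (integral) "int32" else "double"
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    paste0("spacings: ", paste(rep(voxel_size_mm, 3), collapse = " ")),
    "encoding: raw",
    "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.vector(data), con, size = if (integral) 4L else 8L,
           endian = "little")
}

isotropic_spacing <- function(sp, path) {
  sp <- sp[is.finite(sp)]
  if (length(sp) != 3L) stop(path, ": expected 3 spacings")
  if (diff(range(sp)) > 1e-6 * mean(sp))
    stop(path, ": anisotropic voxel spacing (", paste(signif(sp, 6),
         collapse = " x "), ") is not supported; resample before import")
  mean(sp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- MetaImage (mhd + raw) --------------------------------------------------

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], "\\s*=\\s*")
  fields <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = " = "), character(1)),
    tolower(vapply(kv, `[[`, character(1), 1))
  )
  fld <- function(key) if (key %in% names(fields)) fields[[key]] else NULL
  if (!identical(as.integer(fld("ndims")), 3L))
    stop(path, ": only NDims = 3 MetaImage volumes are supported")
  sizes <- as.integer(strsplit(fld("dimsize"), "\\s+")[[1]])
  etype <- toupper(fld("elementtype"))
  ti <- switch(etype,
    MET_DOUBLE = list(size = 8, what = "double", signed = TRUE),
    MET_FLOAT  = list(size = 4, what = "double", signed = TRUE),
    MET_INT    = list(size = 4, what = "integer", signed = TRUE),
    MET_SHORT  = list(size = 2, what = "integer", signed = TRUE),
    MET_USHORT = list(size = 2, what = "integer", signed = FALSE),
    MET_UCHAR  = list(size = 1, what = "integer", signed = FALSE),
    stop(path, ": unsupported ElementType ", etype)
  )
  msb <- toupper(fld("byteordermsb") %||% "FALSE") == "TRUE"
  vs <- NULL
  if (!is.null(fld("elementspacing")))
    vs <- isotropic_spacing(
      as.numeric(strsplit(fld("elementspacing"), "\\s+")[[1]]), path)
  datafile <- fld("elementdatafile")
  if (is.null(datafile)) stop(path, ": missing ElementDataFile")
  rawpath <- file.path(dirname(path), datafile)
  if (!file.exists(rawpath)) stop(path, ": data file ", rawpath, " not found")
  con <- file(rawpath, "rb")
  on.exit(close(con))
  n <- prod(sizes)
  raw <- readBin(con, what = ti$what, n = n, size = ti$size,
                 signed = ti$signed, endian = if (msb) "big" else "little")
  if (length(raw) != n) stop(rawpath, ": truncated MetaImage data")
  list(data = array(raw, sizes), voxel_size_mm = vs)
}

write_mhd <- function(data, voxel_size_mm, path, integral) {
  rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    paste0("DimSize = ", paste(dim(data), collapse = " ")),
    paste0("ElementType = ", if (integral) "MET_INT" else "MET_DOUBLE"),
    paste0("ElementSpacing = ", paste(rep(voxel_size_mm, 3), collapse = " ")),
    "ByteOrderMSB = False",
    paste0("ElementDataFile = ", rawname)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  writeBin(as.vector(data), con, size = if (integral) 4L else 8L,
           endian = "little")
}

# ---- TIFF stacks ------------------------------------------------------------

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  if (length(d2) != 2L)
    stop(path, ": expected single-channel greyscale TIFF pages")
  # page k is slice z = k, stored [y, x]; transpose into canonical [x, y]
  arr <- array(0, c(d2[2], d2[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  list(data = arr, voxel_size_mm = NULL)
}

write_tiff_stack <- function(data, path) {
  if (min(data) < 0 || max(data) > 65535 ||
      max(abs(data - round(data))) > 1e-9)
    stop("TIFF output supports integer greyscale in 0..65535 only; ",
         "use .nrrd or .mhd for float volumes")
  pages <- lapply(seq_len(dim(data)[3]),
                  function(k) t(round(data[, , k])) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
}

# ---- trait tables -----------------------------------------------------------

#' Trait table column schema
#'
#' Column names of the per-nut trait table produced by [measure_walnut()] and
#' consumed by the statistics functions, together with the descriptive names
#' used in reports. The fourteen traits: nut length L, face diameter F,
#' profile diameter P, nut volume Vn, shape factor VA3D (S1), 3D Feret shape
#' (S2), surface area A, sphericity, shell volume Vs, shell thickness T,
#' rugosity, kernel volume Vk, kernel filling ratio R (%), and empty-space
#' volume Ve.
#'
#' @return Named character vector mapping column names to display names.
#' @export
trait_columns <- function() {
  c(L_mm = "Nut length", F_mm = "Nut face diameter",
    P_mm = "Nut profile diameter", Vn_mm3 = "Nut volume",
    VA3D = "Nut shape VA3D", Feret3D = "Nut feret shape 3D",
    A_mm2 = "Nut surface area", Sphericity = "Nut sphericity",
    Vs_mm3 = "Shell volume", T_mm = "Shell thickness",
    Rugosity = "Shell rugosity", Vk_mm3 = "Kernel volume",
    FillingRatio_pct = "Kernel filling ratio", Ve_mm3 = "Empty space volume")
}

#' Read a per-nut trait table from CSV
#'
#' @param path CSV file with a header row containing `accession_id`,
#'   `nut_id` and the fourteen trait columns of [trait_columns()].
#' @return A data.frame with character ids and numeric trait columns.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_trait_table(df, path)
}

#' Write a per-nut trait table to CSV
#'
#' @param table a trait table data.frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trait_table <- function(table, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write ", path, ": directory ", dir,
                             " does not exist")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

validate_trait_table <- function(df, src = "trait table") {
  need <- c("accession_id", "nut_id", names(trait_columns()))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    disp <- trait_columns()[missing]
    lab <- ifelse(is.na(disp), missing, paste0(missing, " (", disp, ")"))
    stop(src, ": missing required column(s): ", paste(lab, collapse = ", "))
  }
  for (col in names(trait_columns())) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      if (anyNA(v) && !all(is.na(df[[col]])))
        stop(src, ": column ", col, " contains non-numeric entries")
      df[[col]] <- v
    }
  }
  df$accession_id <- as.character(df$accession_id)
  df$nut_id <- as.character(df$nut_id)
  if (anyDuplicated(df[c("accession_id", "nut_id")]))
    stop(src, ": duplicated (accession_id, nut_id) pair")
  df
}
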