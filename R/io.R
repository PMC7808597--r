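#' Read a volumetric image or mask
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) via \pkg{RNifti} and uncompressed
#' MetaImage (`.mha`, single-file `.mhd`). Geometry (spacing, origin,
#' direction) is taken from the file header; files whose direction matrix is
#' not orthonormal are rejected. With `as_mask = TRUE` any nonzero voxel
#' becomes 1.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param as_mask read as a binary mask (nonzero -> 1)?
#' @param role mask role tag when `as_mask = TRUE`.
#' @return An [hs_image()] or [hs_mask()].
#' @export
read_volume <- function(path, as_mask = FALSE, role = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*?(\\.nii\\.gz|\\.[a-z0-9]+)$", "\\1", path))
  parsed <- switch(ext,
    ".nii" = , ".nii.gz" = read_nifti_file(path),
    ".mha" = , ".mhd" = read_meta_file(path),
    stop("unsupported format: ", ext,
         " (expected .nii, .nii.gz, .mha or .mhd)"))
  if (as_mask)
    hs_mask(array(as.numeric(parsed$values != 0), dim = dim(parsed$values)),
            parsed$spacing, parsed$origin, parsed$direction, role = role)
  else
    hs_image(parsed$values, parsed$spacing, parsed$origin, parsed$direction)
}

read_nifti_file <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(aff, "try-error")) stop("cannot read NIfTI header of ", path)
  vals <- as.array(img)
  if (length(dim(vals)) > 3L) {
    if (prod(dim(vals)[-(1:3)]) != 1L)
      stop("only scalar 3D volumes are supported: ", path)
    vals <- array(vals, dim = dim(vals)[1:3])
  }
  if (length(dim(vals)) == 2L) vals <- array(vals, dim = c(dim(vals), 1L))
  vals <- array(as.double(vals), dim = dim(vals))
  A <- matrix(aff[1:3, 1:3], 3, 3)
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0)) stop("invalid spacing in ", path)
  direction <- sweep(A, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("non-orthonormal direction matrix in ", path)
  # re-orthonormalize residual rounding from quaternion storage
  sv <- svd(direction)
  direction <- sv$u %*% t(sv$v)
  list(values = vals, spacing = spacing, origin = aff[1:3, 4],
       direction = direction)
}

#' Write a volumetric image or mask
#'
#' Masks are written as unsigned 8-bit, images as 32-bit float. Output format
#' follows the file extension (NIfTI or uncompressed MetaImage).
#'
#' @param x an [hs_image()] or [hs_mask()].
#' @param path destination path (`.nii`, `.nii.gz`, `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  ext <- tolower(sub(".*?(\\.nii\\.gz|\\.[a-z0-9]+)$", "\\1", path))
  switch(ext,
    ".nii" = , ".nii.gz" = write_nifti_file(x, path),
    ".mha" = write_meta_file(x, path),
    stop("unsupported output format: ", ext))
  invisible(path)
}

write_nifti_file <- function(x, path) {
  is_mask <- inherits(x, "hs_mask")
  vals <- x$values
  img <- RNifti::asNifti(vals,
                         datatype = if (is_mask) "uint8" else "double")
  aff <- rbind(cbind(x$direction %*% diag(x$spacing), x$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- MetaImage (.mha/.mhd): plain header + raw voxel block ------------------

meta_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_USHORT = "integer", MET_SHORT = "integer",
                MET_UINT = "integer", MET_INT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
meta_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_USHORT = 2, MET_SHORT = 2,
                MET_UINT = 4, MET_INT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

read_meta_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["NDims"]], "3")) stop("only 3D MetaImage supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  dirkey <- if (!is.null(hdr[["TransformMatrix"]])) "TransformMatrix" else
    if (!is.null(hdr[["Orientation"]])) "Orientation" else NA
  direction <- if (!is.na(dirkey))
    matrix(as.numeric(strsplit(hdr[[dirkey]], "\\s+")[[1]]), 3, 3) else diag(3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4)
    stop("non-orthonormal direction matrix in ", path)
  etype <- hdr[["ElementType"]]
  if (is.null(etype) || !etype %in% names(meta_types))
    stop("unsupported MetaImage ElementType: ", etype)
  compressed <- identical(toupper(hdr[["CompressedData"]] %||% "FALSE"), "TRUE")
  if (compressed) stop("compressed MetaImage data is not supported")
  datafile <- hdr[["ElementDataFile"]]
  n <- prod(dims)
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  what <- meta_types[[etype]]
  vals <- readBin(raw_con, what = what, n = n, size = meta_sizes[[etype]],
                  signed = !etype %in% c("MET_UCHAR", "MET_USHORT"),
                  endian = "little")
  if (length(vals) < n) stop("truncated MetaImage voxel data in ", path)
  list(values = array(as.double(vals), dim = dims), spacing = spacing,
       origin = origin, direction = direction)
}

write_meta_file <- function(x, path) {
  is_mask <- inherits(x, "hs_mask")
  dims <- dim(x$values)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", paste(as.numeric(x$direction),
                                            collapse = " ")),
           paste("Offset =", paste(x$origin, collapse = " ")),
           paste("ElementSpacing =", paste(x$spacing, collapse = " ")),
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementType =", if (is_mask) "MET_UCHAR" else "MET_DOUBLE"),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (is_mask)
    writeBin(as.integer(x$values), con, size = 1, endian = "little")
  else
    writeBin(as.numeric(x$values), con, size = 8, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
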