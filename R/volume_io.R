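#' Read a 3D volume with voxel-size metadata
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; via RNifti), MetaImage
#' (`.mha`, `.mhd` + raw; parsed natively, uncompressed only), multipage TIFF
#' with a JSON sidecar (`<stem>.json` carrying `voxel_size_mm` and an optional
#' affine intensity rescale), and raw binary with a JSON header. Whatever the
#' on-disk axis order, the returned volume uses the internal (z, y, x)
#' convention. Anisotropic spacing is rejected: the detection algorithm is
#' parameterised in voxel counts and assumes a single edge length.
#'
#' @param path file path.
#' @param format one of `"nifti"`, `"metaimage"`, `"tiff_stack"`, `"raw"`;
#'   inferred from the extension when `NULL`.
#' @return A [gray_volume()].
#' @seealso [write_volume()], [read_labels()], [write_labels()]
#' @export
read_volume <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    nifti      = read_nifti_volume(path),
    metaimage  = read_metaimage_volume(path),
    tiff_stack = read_tiff_volume(path),
    raw        = read_raw_volume(path),
    stop("unknown format: ", format))
}

#' Write a 3D volume
#'
#' @inheritParams read_volume
#' @param vol a [gray_volume()].
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot(inherits(vol, "cg_volume"))
  format <- format %||% infer_format(path)
  switch(format,
    nifti      = write_nifti_volume(vol, path),
    metaimage  = write_metaimage_volume(vol$data, vol$voxel_size_mm,
                                        vol$origin_mm, path, "MET_DOUBLE"),
    tiff_stack = write_tiff_volume(vol, path),
    raw        = write_raw_volume(vol$data, vol$voxel_size_mm, vol$origin_mm,
                                  path, "double"),
    stop("unknown format: ", format))
  invisible(path)
}

#' Read / write integer label maps
#'
#' `write_labels()` enforces the contiguity invariant (labels `1..K` with no
#' gaps): depending on `gap_policy` a gappy map is renumbered with a warning
#' (default) or rejected. Round trips are bit-exact for every format.
#'
#' @param labels a [label_volume()].
#' @inheritParams read_volume
#' @param gap_policy `"renumber"` (warn and compact labels) or `"error"`.
#' @return `write_labels()` returns `path` invisibly; `read_labels()` a
#'   [label_volume()].
#' @export
write_labels <- function(labels, path, format = NULL,
                         gap_policy = c("renumber", "error")) {
  stopifnot(inherits(labels, "cg_labels"))
  gap_policy <- match.arg(gap_policy)
  dat <- labels$data
  u <- sort(unique(as.integer(dat[dat > 0L])))
  if (length(u) && !identical(u, seq_len(max(u)))) {
    if (gap_policy == "error")
      stop("label map has gaps (", paste(u, collapse = ","),
           ") and gap_policy = \"error\"")
    warning("renumbering non-contiguous labels on write", call. = FALSE)
    dat[] <- match(as.integer(dat), c(0L, u)) - 1L
  }
  format <- format %||% infer_format(path)
  switch(format,
    nifti      = write_nifti_labels(dat, labels$voxel_size_mm, path),
    metaimage  = write_metaimage_volume(dat, labels$voxel_size_mm,
                                        labels$origin_mm, path, "MET_INT"),
    tiff_stack = write_tiff_labels(dat, labels$voxel_size_mm, path),
    raw        = write_raw_volume(dat, labels$voxel_size_mm, labels$origin_mm,
                                  path, "integer"),
    stop("unknown format: ", format))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, format = NULL) {
  v <- read_volume(path, format)
  dat <- round(v$data)
  if (max(abs(dat - v$data)) > 1e-6)
    stop("volume does not contain integer labels")
  label_volume(dat, v$voxel_size_mm, v$origin_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.(mha|mhd)$", p)) return("metaimage")
  if (grepl("\\.tiff?$", p)) return("tiff_stack")
  if (grepl("\\.raw$", p)) return("raw")
  stop("cannot infer format from path: ", path)
}

assert_isotropic <- function(sp) {
  sp <- as.numeric(sp)
  if (length(sp) < 3) stop("volume metadata lacks 3D spacing")
  sp <- sp[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or non-positive voxel size in metadata")
  if (diff(range(sp)) > 1e-4 * mean(sp))
    stop("unsupported geometry: anisotropic voxel spacing (",
         paste(signif(sp, 6), collapse = " x "), " mm)")
  mean(sp)
}

## ---- NIfTI (RNifti stores arrays as (x, y, z); internal order is (z, y, x))

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  # NIfTI stores pixdim as 32-bit float; recover the intended decimal value
  vs <- signif(assert_isotropic(RNifti::pixdim(img)[1:3]), 7)
  arr <- aperm(unclass(img)[, , , drop = FALSE], c(3, 2, 1))
  org <- as.numeric(RNifti::origin(img))
  gray_volume(arr, vs, origin_mm = rev((1 - org) * vs))
}

write_nifti_volume <- function(vol, path) {
  arr <- aperm(vol$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vol$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
}

write_nifti_labels <- function(dat, vs, path) {
  arr <- aperm(dat, c(3, 2, 1))
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(vs, 3)
  RNifti::writeNifti(img, path, datatype = "int32")
}

## ---- MetaImage (.mha combined / .mhd + .raw); x varies fastest on disk

mi_types <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
              MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3")) stop("MetaImage NDims must be 3")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])   # (nx, ny, nz)
  sp <- hdr$ElementSpacing %||% hdr$ElementSize
  if (is.null(sp)) stop("missing voxel size: no ElementSpacing in header")
  vs <- assert_isotropic(strsplit(sp, "\\s+")[[1]])
  org <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  if (!type %in% names(mi_types)) stop("unsupported ElementType: ", type)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- read_mi_payload(con, n, type)
  } else {
    dpath <- file.path(dirname(path), hdr$ElementDataFile)
    con2 <- file(dpath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- read_mi_payload(con2, n, type)
  }
  arr <- aperm(array(raw, dim = dims), c(3, 2, 1))          # -> (z, y, x)
  gray_volume(arr, vs, origin_mm = rev(org))
}

read_mi_payload <- function(con, n, type) {
  sz <- mi_types[[type]]
  what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "double" else "integer"
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  readBin(con, what = what, n = n, size = sz, signed = signed,
          endian = "little")
}

write_metaimage_volume <- function(dat, vs, org, path, type) {
  arr <- aperm(dat, c(3, 2, 1))                             # -> (x, y, z)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %d %d %d", dim(arr)[1], dim(arr)[2], dim(arr)[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g", vs, vs, vs),
           sprintf("Offset = %.9g %.9g %.9g", org[3], org[2], org[1]),
           paste0("ElementType = ", type))
  sz <- mi_types[[type]]
  if (grepl("\\.mha$", tolower(path))) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.vector(arr), con, size = sz, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste0("ElementDataFile = ", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(as.vector(arr), con, size = sz, endian = "little")
  }
  invisible(path)
}

## ---- multipage TIFF + JSON sidecar --------------------------------------
## TIFF samples are stored in [0, 1]; an affine intensity rescale recorded in
## the sidecar makes the round trip faithful to within 32-bit float precision
## (~1e-7 of the intensity range).

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

read_tiff_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar with voxel size: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_mm))
    stop("sidecar lacks voxel_size_mm: ", sc)
  vs <- assert_isotropic(rep(as.numeric(meta$voxel_size_mm), 3))
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d2 <- dim(slices[[1]])
  arr <- array(0, c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  scale <- meta$intensity_scale %||% 1
  offset <- meta$intensity_offset %||% 0
  gray_volume(arr * scale + offset, vs,
              origin_mm = as.numeric(meta$origin_mm %||% c(0, 0, 0)))
}

write_tiff_volume <- function(vol, path) {
  rng <- range(vol$data)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  norm <- (vol$data - rng[1]) / scale
  slices <- lapply(seq_len(dim(norm)[1]), function(i) norm[i, , ])
  tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(voxel_size_mm = vol$voxel_size_mm, origin_mm = vol$origin_mm,
         intensity_scale = scale, intensity_offset = rng[1]),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_tiff_labels <- function(dat, vs, path) {
  if (max(dat) > 65535L) stop("TIFF label maps support at most 65535 labels")
  slices <- lapply(seq_len(dim(dat)[1]), function(i) dat[i, , ] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxel_size_mm = vs, origin_mm = c(0, 0, 0),
         intensity_scale = 65535, intensity_offset = 0),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- raw binary + JSON header (lossless for double and int32) ------------

read_raw_volume <- function(path) {
  hp <- sidecar_path(path)
  if (!file.exists(hp)) stop("missing JSON header: ", hp)
  hdr <- jsonlite::read_json(hp, simplifyVector = TRUE)
  if (is.null(hdr$voxel_size_mm) || as.numeric(hdr$voxel_size_mm) <= 0)
    stop("missing or zero voxel size in header")
  dims <- as.integer(hdr$dim)                               # (nz, ny, nx)
  dtype <- hdr$dtype %||% "double"
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- if (dtype == "double") {
    readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  } else if (dtype == "int32") {
    readBin(con, "integer", n = prod(dims), size = 4, endian = "little")
  } else stop("unsupported dtype: ", dtype)
  gray_volume(array(vals, dims), as.numeric(hdr$voxel_size_mm),
              origin_mm = as.numeric(hdr$origin_mm %||% c(0, 0, 0)))
}

write_raw_volume <- function(dat, vs, org, path, mode) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (mode == "double") {
    writeBin(as.vector(as.double(dat)), con, size = 8, endian = "little")
    dtype <- "double"
  } else {
    writeBin(as.vector(as.integer(dat)), con, size = 4, endian = "little")
    dtype <- "int32"
  }
  jsonlite::write_json(
    list(dim = dim(dat), voxel_size_mm = vs, origin_mm = org, dtype = dtype),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
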