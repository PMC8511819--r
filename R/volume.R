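#' Image volume container
#'
#' A 3-D scalar grid (Hounsfield units for CT-like volumes, or any other
#' per-voxel scalar such as calibrated density) together with its voxel
#' spacing and origin. The origin is the physical position (mm) of the centre
#' of voxel `[1, 1, 1]`.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin Numeric length-3, mm; default `c(0, 0, 0)`.
#' @return An object of class `image_volume` (list with `data`, `spacing`,
#'   `origin`).
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @exportS3Method base::print
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %s mm, range [%.6g, %.6g]\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical coordinates of voxel centres along each axis
#' @param vol An `image_volume`.
#' @return List of 3 numeric vectors (mm).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
}

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.(mha|mhd)$", path)) "metaimage"
  else stop("cannot infer volume format from path: ", path)
}

#' Write an image or label volume to NIfTI or MetaImage
#'
#' NIfTI goes through the RNifti library; MetaImage (.mha single file, local
#' raw data, or .mhd header + .raw pair) is written directly. Data are stored
#' as float64 so that round trips are bit-exact; integer label volumes are
#' stored as int32.
#'
#' @param vol An `image_volume` (or a plain integer 3-D array for labels, with
#'   `spacing`/`origin` taken from `ref`).
#' @param path Output file path; extension selects the layout.
#' @param format `"nifti"`, `"metaimage"`, or `NULL` to infer from `path`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  if (is.null(format)) format <- guess_format(path)
  if (!format %in% c("nifti", "metaimage"))
    stop("unknown volume format: ", format)
  if (format == "nifti") {
    img <- RNifti::asNifti(vol$data)
    img <- RNifti::`pixdim<-`(img, vol$spacing)
    # qform: axis-aligned RAS with the stated origin
    RNifti::qform(img) <- structure(
      rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1)), code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    write_metaimage(vol, path)
  }
  invisible(path)
}

#' Read a NIfTI or MetaImage volume written by [write_volume()]
#'
#' @param path File path (.nii, .nii.gz, .mha, .mhd).
#' @param format Optional explicit format.
#' @return An `image_volume`.
#' @export
read_volume <- function(path, format = NULL) {
  if (is.null(format)) format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    spacing <- attr(RNifti::niftiHeader(img), "pixdim")[2:4]
    if (is.null(spacing)) spacing <- RNifti::pixdim(img)
    xf <- RNifti::xform(img)
    origin <- xf[1:3, 4]
    image_volume(array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img), origin = origin)
  } else if (format == "metaimage") {
    read_metaimage(path)
  } else stop("unknown volume format: ", format)
}

# -- MetaImage (ITK MetaIO) ---------------------------------------------------

write_metaimage <- function(vol, path) {
  is_int <- is.integer(vol$data)
  type <- if (is_int) "MET_INT" else "MET_DOUBLE"
  d <- dim(vol$data)
  local <- grepl("\\.mha$", path)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementType =", type)
  )
  if (local) {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(vol$data), con,
             size = if (is_int) 4L else 8L, endian = "little")
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path))
    hdr <- c(hdr, paste("ElementDataFile =", raw_name))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.vector(vol$data), con,
             size = if (is_int) 4L else 8L, endian = "little")
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  n <- prod(d)
  read_payload <- function(c2) {
    if (type == "MET_DOUBLE") readBin(c2, "double", n = n, size = 8L, endian = "little")
    else if (type == "MET_INT") readBin(c2, "integer", n = n, size = 4L, endian = "little")
    else stop("unsupported MetaImage ElementType: ", type)
  }
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    data <- read_payload(con)
  } else {
    con2 <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(con2), add = TRUE)
    data <- read_payload(con2)
  }
  image_volume(array(data, dim = d), spacing = spacing, origin = origin)
}
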