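# Minimal multi-page 32-bit-float TIFF I/O (little-endian, uncompressed,
# one strip per page) plus JSON sidecars.  No TIFF library is available in
# the target environment, so the container format is written directly; the
# layout is deliberately plain (baseline tags only) so standard readers
# (tifffile, ImageJ) open these files.

.tiff_tag_ids <- c(ImageWidth = 256L, ImageLength = 257L,
                   BitsPerSample = 258L, Compression = 259L,
                   Photometric = 262L, StripOffsets = 273L,
                   SamplesPerPixel = 277L, RowsPerStrip = 278L,
                   StripByteCounts = 279L, SampleFormat = 339L)

#' Write a 3D volume as a multi-page float TIFF
#'
#' Pages are z slices; within a page, rows advance along y and columns
#' along x (axis convention: volumes are indexed [x, y, z] in R with z
#' along the view-A detection axis).
#'
#' @param volume 3D numeric array (nx, ny, nz).
#' @param path output file path.
#' @export
writeVolumeTiff <- function(volume, path) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3D array")
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size,
                                  endian = "little")
  writeChar("II", con, nchars = 2L, eos = NULL)
  w(42L, 2L)
  stripBytes <- nx * ny * 4L
  # layout: header (8) | page data blocks | IFDs
  dataOff <- 8L
  ifdOff <- dataOff + nz * stripBytes
  w(ifdOff, 4L)                 # offset of first IFD
  for (z in seq_len(nz)) {
    # row-major page of width nx: R's column-major [x, y] layout already
    # streams x fastest
    writeBin(as.numeric(volume[, , z]), con, size = 4L, endian = "little")
  }
  nTags <- 10L
  ifdSize <- 2L + nTags * 12L + 4L
  for (z in seq_len(nz)) {
    w(nTags, 2L)
    tag <- function(id, type, count, value) {
      w(id, 2L); w(type, 2L); w(count, 4L)
      if (type == 3L) { w(value, 2L); w(0L, 2L) } else w(value, 4L)
    }
    tag(256L, 3L, 1L, nx)                         # ImageWidth
    tag(257L, 3L, 1L, ny)                         # ImageLength
    tag(258L, 3L, 1L, 32L)                        # BitsPerSample
    tag(259L, 3L, 1L, 1L)                         # Compression: none
    tag(262L, 3L, 1L, 1L)                         # Photometric: BlackIsZero
    tag(273L, 4L, 1L, dataOff + (z - 1L) * stripBytes)  # StripOffsets
    tag(277L, 3L, 1L, 1L)                         # SamplesPerPixel
    tag(278L, 3L, 1L, ny)                         # RowsPerStrip
    tag(279L, 4L, 1L, stripBytes)                 # StripByteCounts
    tag(339L, 3L, 1L, 3L)                         # SampleFormat: float
    nxt <- if (z < nz) ifdOff + z * ifdSize else 0L
    w(nxt, 4L)
  }
  invisible(path)
}

#' Read a multi-page float TIFF volume
#'
#' Accepts the uncompressed single-sample 32-bit-float layout written by
#' \code{\link{writeVolumeTiff}} (and equivalent files from other tools).
#'
#' @param path TIFF file path.
#' @return 3D numeric array (nx, ny, nz).
#' @export
readVolumeTiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  if (!(raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49))) {
    stop("only little-endian TIFF is supported: ", path)
  }
  u16 <- function(off) as.integer(raw[off + 1L]) +
    256L * as.integer(raw[off + 2L])
  u32 <- function(off) as.integer(raw[off + 1L]) +
    256 * as.integer(raw[off + 2L]) + 65536 * as.integer(raw[off + 3L]) +
    16777216 * as.integer(raw[off + 4L])
  if (u16(2L) != 42L) stop("bad TIFF magic in ", path)
  ifd <- u32(4L)
  pages <- list(); nx <- ny <- NULL
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (t in seq_len(n)) {
      base <- ifd + 2L + (t - 1L) * 12L
      id <- u16(base); type <- u16(base + 2L)
      val <- if (type == 3L) u16(base + 8L) else u32(base + 8L)
      tags[[as.character(id)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("missing TIFF tags in ", path)
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
      stop("compressed TIFF not supported: ", path)
    }
    if (!is.null(tags[["258"]]) && tags[["258"]] != 32L ||
        !is.null(tags[["339"]]) && tags[["339"]] != 3L) {
      stop("only 32-bit float TIFF is supported: ", path)
    }
    pw <- tags[["256"]]; ph <- tags[["257"]]
    if (is.null(nx)) { nx <- pw; ny <- ph }
    if (pw != nx || ph != ny) stop("inconsistent page sizes in ", path)
    off <- tags[["273"]]
    vals <- readBin(raw[(off + 1L):(off + tags[["279"]])], "numeric",
                    n = nx * ny, size = 4L, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nx, ny)
    ifd <- u32(ifd + 2L + n * 12L)
  }
  nz <- length(pages)
  out <- array(0, c(nx, ny, nz))
  for (z in seq_len(nz)) out[, , z] <- pages[[z]]
  out
}

# FNV-1a hash of a character string (hex); used for provenance stamps.
# 32-bit arithmetic done in 16-bit limbs so doubles stay exact.
.fnv1a <- function(s) {
  b <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (x in b) {
    lo <- bitwXor(h %% 65536, x %% 256)
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  # %x needs an R integer; emit the 32-bit value as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.sh_ordering_version <- "even-l4-flat-v1"

#' Write an irradiance stack as TIFFs with a JSON sidecar
#'
#' One multi-page float TIFF per measurement
#' (\code{<prefix>_meas###.tif}) plus \code{<prefix>.json} recording the
#' scheme, voxel spacing, noise metadata and a config hash.
#'
#' @param stack an \linkS4class{IrradianceStack}.
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
writeStack <- function(stack, prefix) {
  sp <- stack@scheme@specs
  files <- character(nrow(sp))
  for (p in seq_len(nrow(sp))) {
    files[p] <- paste0(prefix, sprintf("_meas%03d.tif", p))
    writeVolumeTiff(stack@volumes[[p]], files[p])
  }
  meta <- list(
    format = "irradiance-stack",
    axisOrder = "x,y,z (z along view-A detection axis); pages are z",
    voxelSpacingNm = stack@spacingNm,
    scheme = list(name = stack@scheme@name,
                  illumView = sp$illumView, psiRad = sp$psi,
                  tauRad = sp$tau),
    noise = list(model = stack@noiseModel,
                 countsPerUnit = stack@countsPerUnit,
                 seed = stack@seed),
    files = basename(files)
  )
  meta$configHash <- .fnv1a(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA))
  side <- paste0(prefix, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' Read an irradiance stack written by \code{\link{writeStack}}
#'
#' @param prefix path prefix (sidecar at \code{<prefix>.json}).
#' @return an \linkS4class{IrradianceStack}.
#' @export
readStack <- function(prefix) {
  side <- paste0(prefix, ".json")
  if (!file.exists(side)) {
    stop("missing sidecar: expected ", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "irradiance-stack")) {
    stop("sidecar is not an irradiance-stack description: ", side)
  }
  vols <- lapply(file.path(dirname(side), meta$files), readVolumeTiff)
  scheme <- new("MeasurementScheme",
                name = meta$scheme$name,
                specs = data.frame(illumView = meta$scheme$illumView,
                                   psi = meta$scheme$psiRad,
                                   tau = meta$scheme$tauRad))
  new("IrradianceStack", volumes = vols, scheme = scheme,
      spacingNm = meta$voxelSpacingNm,
      countsPerUnit = meta$noise$countsPerUnit,
      noiseModel = meta$noise$model,
      seed = if (is.null(meta$noise$seed)) NA_real_ else
        as.numeric(meta$noise$seed))
}

#' Write an ODF coefficient field (15-channel volume + sidecar)
#'
#' The TIFF holds nz * 15 pages ordered channel-major (all z slices of
#' channel 1, then channel 2, ...); the sidecar records dimensions, voxel
#' spacing and the spherical-harmonic ordering version.
#'
#' @param field an \linkS4class{ODFField}.
#' @param prefix output path prefix.
#' @return sidecar path, invisibly.
#' @export
writeCoefficientField <- function(field, prefix) {
  d <- dim(field@coefficients)
  flat <- array(field@coefficients, c(d[1], d[2], d[3] * 15L))
  tif <- paste0(prefix, "_coeffs.tif")
  writeVolumeTiff(flat, tif)
  meta <- list(
    format = "coefficient-field",
    shOrdering = .sh_ordering_version,
    channels = 15L,
    dims = d[1:3],
    voxelSpacingNm = field@spacingNm,
    originNm = field@originNm,
    axisOrder = "x,y,z; pages are z within each channel, channel-major",
    file = basename(tif)
  )
  meta$configHash <- .fnv1a(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA))
  side <- paste0(prefix, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' Read a coefficient field written by \code{\link{writeCoefficientField}}
#'
#' @param prefix path prefix.
#' @return an \linkS4class{ODFField}.
#' @export
readCoefficientField <- function(prefix) {
  side <- paste0(prefix, ".json")
  if (!file.exists(side)) stop("missing sidecar: expected ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "coefficient-field")) {
    stop("sidecar is not a coefficient-field description: ", side)
  }
  if (!identical(as.integer(meta$channels), 15L)) {
    stop("coefficient field must have 15 channels, found ", meta$channels)
  }
  if (!identical(meta$shOrdering, .sh_ordering_version)) {
    stop("SH ordering version mismatch: file has ", meta$shOrdering,
         ", library uses ", .sh_ordering_version)
  }
  flat <- readVolumeTiff(file.path(dirname(side), meta$file))
  d <- as.integer(meta$dims)
  if (!identical(dim(flat), c(d[1:2], d[3] * 15L))) {
    stop("coefficient volume does not match sidecar dimensions")
  }
  odfField(array(flat, c(d, 15L)), meta$voxelSpacingNm,
           as.numeric(meta$originNm))
}

#' Read / write wire annotations as CSV
#'
#' Columns: x1, y1, z1, x2, y2, z2 (nm), label, diameter_nm.
#'
#' @param wires wire data.frame; @param path CSV path.
#' @export
writeWiresCsv <- function(wires, path) {
  utils::write.csv(wires, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWiresCsv
#' @export
readWiresCsv <- function(path) {
  w <- utils::read.csv(path)
  need <- c("x1", "y1", "z1", "x2", "y2", "z2", "label", "diameter_nm")
  if (!all(need %in% names(w))) {
    stop("wire CSV must have columns ", paste(need, collapse = ", "))
  }
  w
}
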