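#' @section File formats:
#' No TIFF or NIfTI reader is assumed to be installed, so the package
#' carries minimal, self-contained implementations: uncompressed
#' single-sample multi-page TIFF (unsigned 16-bit images, signed 32-bit
#' label volumes) and NIfTI-1 (float32, optional .gz via R's gzip
#' connections).  These cover exactly what the pipeline writes and reads
#' back; they are not general-purpose codecs.
#' @name io-internals
#' @keywords internal
NULL

tiff_type_for <- function(what) {
  switch(what,
         uint16 = list(bits = 16L, sample_format = 1L, size = 2L),
         int32 = list(bits = 32L, sample_format = 2L, size = 4L),
         stop("unsupported TIFF sample type"))
}

#' Write a 3D array as a multi-page TIFF
#'
#' Uncompressed, little-endian, one strip per page; z planes become pages,
#' rows are y, columns are x.
#'
#' @param a 3D array in `(z, y, x)` order.
#' @param path output path.
#' @param what `"uint16"` (image stacks) or `"int32"` (label volumes).
#' @return the path, invisibly.
#' @export
write_tiff_stack <- function(a, path, what = c("uint16", "int32")) {
  what <- match.arg(what)
  tp <- tiff_type_for(what)
  d <- dim(a)
  stopifnot(length(d) == 3)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)   # header; first IFD at 8
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  strip_size <- nx * ny * tp$size
  # layout per page: [IFD][pixel data]
  page_bytes <- ifd_size + strip_size
  for (z in seq_len(nz)) {
    ifd_off <- 8L + (z - 1L) * page_bytes
    data_off <- ifd_off + ifd_size
    next_ifd <- if (z < nz) ifd_off + page_bytes else 0L
    w2(n_entries)
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    entry(256L, 3L, 1L, nx)             # ImageWidth
    entry(257L, 3L, 1L, ny)             # ImageLength
    entry(258L, 3L, 1L, tp$bits)        # BitsPerSample
    entry(259L, 3L, 1L, 1L)             # Compression: none
    entry(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)       # StripOffsets
    entry(278L, 3L, 1L, ny)             # RowsPerStrip
    entry(279L, 4L, 1L, strip_size)     # StripByteCounts
    entry(339L, 3L, 1L, tp$sample_format)  # SampleFormat
    w4(next_ifd)
    plane <- as.vector(t(a[z, , ]))     # row-major: x fastest
    if (what == "uint16") {
      v <- as.integer(round(plane))
      v[v < 0L] <- 0L; v[v > 65535L] <- 65535L
      v[v > 32767L] <- v[v > 32767L] - 65536L   # two's complement
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(round(plane)), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff_stack()]
#'
#' Supports uncompressed single-sample pages with 16-bit unsigned or
#' 32-bit signed data.
#'
#' @param path input path.
#' @return 3D array in `(z, y, x)` order.
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("only little-endian TIFF supported")
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  ifd <- u32(4)
  planes <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base)
      tags[[as.character(tag)]] <- u32(base + 8)
    }
    nx <- tags[["256"]]; ny <- tags[["257"]]
    bits <- tags[["258"]]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stop("compressed TIFF not supported")
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]]
    off <- tags[["273"]]; nbytes <- tags[["279"]]
    size <- bits / 8
    count <- nbytes / size
    if (bits == 16 && fmt == 1) {
      v <- readBin(raw[(off + 1):(off + nbytes)], "integer", n = count,
                   size = 2, signed = FALSE, endian = "little")
    } else if (bits == 32 && fmt == 2) {
      v <- readBin(raw[(off + 1):(off + nbytes)], "integer", n = count,
                   size = 4, endian = "little")
    } else stop("unsupported TIFF sample layout")
    planes[[length(planes) + 1]] <- t(matrix(v, nrow = nx, ncol = ny))
    ifd <- u32(ifd + 2 + n * 12)
  }
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  out <- array(0, dim = c(length(planes), ny, nx))
  for (z in seq_along(planes)) out[z, , ] <- planes[[z]]
  out
}

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' Float32, little-endian, `n+1` magic with data at offset 352.  3D arrays
#' are interpreted as `(z, y, x)` and written with x fastest (standard
#' NIfTI layout); 4D arrays `(z, y, x, c)` keep the component axis last.
#'
#' @param a 3D or 4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size `(dz, dy, dx)` in the units of `a` (stored in mm
#'   fields as-is; this package works in um throughout).
#' @return the path, invisibly.
#' @export
write_nifti <- function(a, path, voxel_size = c(1, 1, 1)) {
  d <- dim(a)
  stopifnot(length(d) %in% c(3, 4))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  ndim <- length(d)
  if (ndim == 3) {
    ap <- aperm(a, c(3, 2, 1))
    dims <- c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L)
  } else {
    ap <- aperm(a, c(3, 2, 1, 4))
    dims <- c(4L, d[3], d[2], d[1], d[4], 1L, 1L, 1L)
  }
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                      # unused through dim_info
  w(as.integer(dims), 2)                      # dim[8]
  w(rep(0, 3), 4)                             # intent_p1..p3
  w(0L, 2)                                    # intent_code
  w(16L, 2)                                   # datatype = float32
  w(32L, 2)                                   # bitpix
  w(0L, 2)                                    # slice_start
  pix <- c(1, voxel_size[3], voxel_size[2], voxel_size[1], 1, 1, 1, 1)
  w(pix, 4)                                   # pixdim[8]
  w(352, 4)                                   # vox_offset (float)
  w(c(1, 0), 4)                               # scl_slope, scl_inter
  w(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end, codes
  w(c(0, 0, 0), 4)                            # cal_max, cal_min, slice_dur
  w(0, 4)                                     # toffset
  w(c(0L, 0L), 4)                             # glmax, glmin
  writeBin(raw(80 + 24), con)                 # descrip, aux_file
  w(c(0L, 1L), 2)                             # qform_code, sform_code = 1
  w(rep(0, 6), 4)                             # quatern b c d, qoffset x y z
  srow <- rbind(c(voxel_size[3], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[1], 0))
  w(as.numeric(t(srow)), 4)                   # srow_x, srow_y, srow_z
  writeBin(charToRaw(sprintf("%-16s", "")), con)  # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)   # magic
  writeBin(raw(4), con)                       # extension flag
  w(as.numeric(ap), 4)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return list with `data` (array in `(z, y, x[, c])` order) and
#'   `voxel_size` `(dz, dy, dx)`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  rint <- function(off, size, n = 1, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rflt <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (rint(0, 4) != 348L) stop("not a NIfTI-1 file")
  dims <- rint(40, 2, 8)
  datatype <- rint(70, 2)
  if (datatype != 16L) stop("only float32 NIfTI supported")
  pix <- rflt(76, 8)
  ndim <- dims[1]
  d <- dims[2:(1 + ndim)]
  vox_offset <- rflt(108)
  if (vox_offset > 352) readBin(con, "raw", n = vox_offset - 352)
  v <- readBin(con, "double", n = prod(d), size = 4, endian = "little")
  a <- array(v, dim = d)
  a <- if (ndim == 3) aperm(a, c(3, 2, 1)) else aperm(a, c(3, 2, 1, 4))
  list(data = a, voxel_size = c(pix[4], pix[3], pix[2]))
}

#' Write / read the standard nucleus-table CSV
#'
#' Columns: `animal_id, position_id, timepoint, nucleus_id, x_um, y_um,
#' z_um, volume_voxels, volume_um3`.
#'
#' @param table a [nucleus_table()].
#' @param path CSV path.
#' @return `write_nucleus_csv`: the path, invisibly; `read_nucleus_csv`:
#'   a [nucleus_table()].
#' @export
write_nucleus_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nucleus_csv
#' @export
read_nucleus_csv <- function(path) {
  nucleus_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read the fiducial-coordinate CSV
#'
#' Columns: `animal_id, position_id, timepoint, fiducial_id, x_um, y_um,
#' z_um`.
#'
#' @param table fiducial data frame.
#' @param path CSV path.
#' @return `write_fiducial_csv`: the path, invisibly; `read_fiducial_csv`:
#'   a data frame.
#' @export
write_fiducial_csv <- function(table, path) {
  need <- c("animal_id", "position_id", "timepoint", "fiducial_id",
            "x_um", "y_um", "z_um")
  stopifnot(all(need %in% names(table)))
  write.csv(table[need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducial_csv
#' @export
read_fiducial_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
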