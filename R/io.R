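#' Read a 3D volume from NIfTI-1, NRRD or multi-page TIFF
#'
#' Minimal readers written against the format subsets this package writes
#' and the common cases produced by scientific tools: uncompressed or
#' gzipped NIfTI-1 (`.nii`, `.nii.gz`), NRRD (`.nrrd`, raw or gzip encoding,
#' attached data) and baseline uncompressed grayscale multi-page TIFF
#' (`.tif`, `.tiff`). TIFF carries no reliable spacing, so `spacing` must be
#' supplied for it.
#'
#' @param path file to read.
#' @param format_hint optional `"nifti"`, `"nrrd"` or `"tiff"`; guessed from
#'   the extension when `NULL`.
#' @param spacing optional per-axis voxel size (mm) overriding the header
#'   (mandatory for TIFF).
#' @param frame_tag tag stored on the returned volume.
#' @return a [pa_volume].
#' @export
read_volume <- function(path, format_hint = NULL, spacing = NULL,
                        frame_tag = "volume") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  fmt <- if (is.null(format_hint)) guess_format(path) else match.arg(
    tolower(format_hint), c("nifti", "nrrd", "tiff"))
  r <- switch(fmt,
    nifti = read_nifti(path),
    nrrd  = read_nrrd(path),
    tiff  = read_tiff(path)
  )
  sp <- if (!is.null(spacing)) spacing else r$spacing
  if (is.null(sp)) {
    stop(sprintf("%s carries no voxel spacing; pass `spacing` explicitly", fmt),
         call. = FALSE)
  }
  nbad <- sum(!is.finite(r$data))
  if (nbad > 0L) {
    stop(sprintf("volume in %s contains %d non-finite voxel(s)", path, nbad),
         call. = FALSE)
  }
  pa_volume(r$data, spacing = sp, frame_tag = frame_tag)
}

#' Write a volume to NIfTI-1, NRRD or multi-page TIFF
#'
#' Values are stored as 64-bit IEEE floats in every format, so a write/read
#' round trip reproduces intensities bit-for-bit.
#'
#' @param volume a [pa_volume].
#' @param path destination; extension decides the format unless
#'   `format_hint` is given (`.nii.gz` gzips the NIfTI stream).
#' @inheritParams read_volume
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format_hint = NULL) {
  stopifnot(is_pa_volume(volume))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("parent directory does not exist: %s", dir), call. = FALSE)
  }
  fmt <- if (is.null(format_hint)) guess_format(path) else match.arg(
    tolower(format_hint), c("nifti", "nrrd", "tiff"))
  ok <- tryCatch({
    switch(fmt,
      nifti = write_nifti(volume, path),
      nrrd  = write_nrrd(volume, path),
      tiff  = write_tiff(volume, path)
    )
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

guess_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.nrrd$", p)) return("nrrd")
  if (grepl("\\.tiff?$", p)) return("tiff")
  stop(sprintf("cannot guess volume format from '%s' (use format_hint)", path),
       call. = FALSE)
}

# ---- NIfTI-1 -----------------------------------------------------------

nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header")
  endian <- "little"
  szh <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic string")
  dimv <- readBin(hdr[41:56], "integer", n = 8L, size = 2L, endian = endian)
  ndim <- dimv[1]
  if (ndim < 3L) stop("NIfTI volume is not 3D")
  shp <- dimv[2:4]
  extra <- if (ndim > 3L) dimv[5:(ndim + 1)] else integer(0)
  if (length(extra) && any(extra > 1L)) {
    stop("NIfTI file has more than one 3D frame; only scalar 3D supported")
  }
  datatype <- readBin(hdr[71:72], "integer", size = 2L, endian = endian)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d", datatype))
  pixdim <- readBin(hdr[77:108], "double", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(hdr[109:112], "double", size = 4L, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", size = 4L, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", size = 4L, endian = endian)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(shp)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data section")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = shp), spacing = abs(pixdim[2:4]))
}

write_nifti <- function(volume, path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb")
         else file(path, "wb")
  on.exit(close(con))
  shp <- volume$shape
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(c(3L, shp, 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..3
  w_i16(0L)                        # intent_code
  w_i16(64L)                       # datatype: float64
  w_i16(64L)                       # bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, volume$spacing, 1, 1, 1, 1))  # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)             # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(80L); w_raw(24L)           # descrip, aux_file
  w_i16(0L); w_i16(1L)             # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))       # quatern/qoffset
  w_f32(c(volume$spacing[1], 0, 0, 0))  # srow_x
  w_f32(c(0, volume$spacing[2], 0, 0))  # srow_y
  w_f32(c(0, 0, volume$spacing[3], 0))  # srow_z
  w_raw(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                        # extension flag
  writeBin(as.double(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

# ---- NRRD --------------------------------------------------------------

nrrd_types <- list(
  "double" = list(what = "double", size = 8L, signed = TRUE),
  "float"  = list(what = "double", size = 4L, signed = TRUE),
  "int"    = list(what = "integer", size = 4L, signed = TRUE),
  "short"  = list(what = "integer", size = 2L, signed = TRUE),
  "uchar"  = list(what = "integer", size = 1L, signed = FALSE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  read_line_raw <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  magic <- read_line_raw()
  if (!grepl("^NRRD000[1-9]$", magic)) stop("not an NRRD file")
  fields <- list()
  repeat {
    ln <- read_line_raw()
    if (identical(ln, "")) break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexpr(":=?", ln), invert = TRUE)[[1]]
    if (length(kv) < 2L) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.null(ndim) || ndim != 3L) stop("only 3D NRRD supported")
  shp <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  typ <- nrrd_types[[fields[["type"]]]]
  if (is.null(typ)) stop(sprintf("unsupported NRRD type '%s'", fields[["type"]]))
  enc <- tolower(fields[["encoding"]] %||% "raw")
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(rows, function(r) {
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]])
    }, numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  n <- prod(shp)
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(enc, "gzip") || identical(enc, "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (!identical(enc, "raw")) {
    stop(sprintf("unsupported NRRD encoding '%s'", enc))
  }
  vals <- readBin(payload, typ$what, n = n, size = typ$size,
                  signed = typ$signed, endian = endian)
  if (length(vals) < n) stop("truncated NRRD data section")
  list(data = array(as.double(vals), dim = shp), spacing = spacing)
}

write_nrrd <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "NRRD0004\n",
    "# vesselreg volume\n",
    "type: double\n",
    "dimension: 3\n",
    sprintf("sizes: %d %d %d\n", volume$shape[1], volume$shape[2],
            volume$shape[3]),
    sprintf("spacings: %.17g %.17g %.17g\n", volume$spacing[1],
            volume$spacing[2], volume$spacing[3]),
    "endian: little\n",
    "encoding: raw\n",
    "\n")
  writeBin(charToRaw(hdr), con)
  writeBin(as.double(volume$data), con, size = 8L, endian = "little")
  invisible(path)
}

# ---- baseline multi-page TIFF ------------------------------------------
# Grayscale, one strip per page, 64-bit IEEE float samples, little-endian.

read_tiff <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", n = sz)
  order <- rawToChar(buf[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big"
            else stop("not a TIFF file")
  u16 <- function(off) readBin(buf[(off + 1):(off + 2)], "integer", size = 2L,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(buf[(off + 1):(off + 4)], "integer", size = 4L,
                               endian = endian)
  if (u16(2) != 42L) stop("bad TIFF magic number")
  ifd_off <- u32(4)
  slices <- list()
  width <- height <- NULL
  while (ifd_off != 0L) {
    nent <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(nent)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- u16(e); typ <- u16(e + 2); cnt <- u32(e + 4)
      val <- if (typ == 3L && cnt == 1L) u16(e + 8) else u32(e + 8)
      tags[[as.character(tag)]] <- list(type = typ, count = cnt, value = val)
    }
    gv <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    w <- gv(256); h <- gv(257)
    bps <- gv(258, 1L); comp <- gv(259, 1L); sf <- gv(339, 1L)
    if (comp != 1L) stop("only uncompressed TIFF supported")
    if (!(bps %in% c(32L, 64L)) || sf != 3L) {
      stop("only 32/64-bit float grayscale TIFF supported")
    }
    spp <- gv(277, 1L)
    if (spp != 1L) stop("only single-sample (grayscale) TIFF supported")
    # strip offsets/counts may be inline (count 1) or in an array
    so <- tags[["273"]]; sc <- tags[["279"]]
    offs <- if (so$count == 1L) so$value else
      vapply(seq_len(so$count) - 1L,
             function(k) u32(so$value + 4L * k), integer(1))
    cnts <- if (sc$count == 1L) sc$value else
      vapply(seq_len(sc$count) - 1L,
             function(k) u32(sc$value + 4L * k), integer(1))
    bytes <- unlist(lapply(seq_along(offs), function(k) {
      buf[(offs[k] + 1):(offs[k] + cnts[k])]
    }))
    vals <- readBin(bytes, "double", n = w * h, size = bps %/% 8L,
                    endian = endian)
    if (!is.null(width) && (w != width || h != height)) {
      stop("TIFF pages have inconsistent dimensions")
    }
    width <- w; height <- h
    slices[[length(slices) + 1L]] <- vals
    ifd_off <- u32(ifd_off + 2 + nent * 12)
  }
  if (length(slices) < 2L) stop("TIFF volume needs at least 2 pages")
  data <- array(unlist(slices), dim = c(width, height, length(slices)))
  list(data = data, spacing = NULL)
}

write_tiff <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  shp <- volume$shape
  w <- shp[1]; h <- shp[2]; np <- shp[3]
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L)
  strip_bytes <- w * h * 8L
  data_start <- 8L
  ifd_start <- data_start + np * strip_bytes
  w32(ifd_start)                    # first IFD offset
  for (k in seq_len(np)) {
    writeBin(as.double(volume$data[, , k]), con, size = 8L, endian = "little")
  }
  nent <- 9L
  ifd_size <- 2L + nent * 12L + 4L
  entry <- function(tag, typ, cnt, val) {
    w16(tag); w16(typ); w32(cnt)
    if (typ == 3L) { w16(val); w16(0L) } else w32(val)
  }
  for (k in seq_len(np)) {
    w16(nent)                                    # entry count
    entry(256L, 4L, 1L, w)                       # ImageWidth
    entry(257L, 4L, 1L, h)                       # ImageLength
    entry(258L, 3L, 1L, 64L)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_start + (k - 1L) * strip_bytes)  # StripOffsets
    entry(278L, 4L, 1L, h)                       # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, 3L)                      # SampleFormat: IEEE float
    nxt <- if (k < np) ifd_start + k * ifd_size else 0L
    w32(nxt)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
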