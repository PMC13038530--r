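# Readers/writers: MetaImage (.mha/.mhd) and NRRD volumes via minimal
# format-conforming implementations, NIfTI via RNifti, 16-bit radiographs
# (TIFF, optionally PNG) with a mandatory JSON sidecar carrying domain,
# geometry and quantization scale, and report serialization.

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.mhd$", low)) "mhd" else if (grepl("\\.mha$", low)) "mha"
  else if (grepl("\\.nrrd$", low)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else stop("unsupported volume format: ", basename(path),
            " (expected .mha/.mhd, .nrrd, .nii or .nii.gz)")
}

#' Write a volume to disk
#'
#' Supported formats by extension: MetaImage (`.mha` single-file, `.mhd` +
#' raw sibling), NRRD (`.nrrd`) and NIfTI (`.nii`, `.nii.gz`). Values are
#' stored as 64-bit floats (32-bit for NIfTI), spacing and origin to full
#' precision; the package's LPS-style axis convention is mapped to NIfTI's
#' RAS+ on write and back on read.
#'
#' @param volume a [voxel_volume()], [attenuation_volume()] or
#'   [label_mask()].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  fmt <- volume_format(path)
  vals <- as.numeric(volume$values)
  dims <- dim(volume$values)
  if (fmt %in% c("mha", "mhd")) {
    datafile <- if (fmt == "mha") "LOCAL" else
      paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
    header <- paste0(
      "ObjectType = Image\n",
      "NDims = 3\n",
      "BinaryData = True\n",
      "BinaryDataByteOrderMSB = False\n",
      "CompressedData = False\n",
      "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
      "Offset = ", paste(format(volume$origin, digits = 17), collapse = " "), "\n",
      "ElementSpacing = ", paste(format(volume$spacing, digits = 17), collapse = " "), "\n",
      "DimSize = ", paste(dims, collapse = " "), "\n",
      "ElementType = MET_DOUBLE\n",
      "ElementDataFile = ", datafile, "\n")
    con <- file(path, "wb")
    writeChar(header, con, eos = NULL)
    if (fmt == "mha") writeBin(vals, con, size = 8, endian = "little")
    close(con)
    if (fmt == "mhd") {
      rawcon <- file(file.path(dirname(path), datafile), "wb")
      writeBin(vals, rawcon, size = 8, endian = "little")
      close(rawcon)
    }
  } else if (fmt == "nrrd") {
    header <- paste0(
      "NRRD0004\n",
      "type: double\n",
      "dimension: 3\n",
      "sizes: ", paste(dims, collapse = " "), "\n",
      "spacings: ", paste(format(volume$spacing, digits = 17), collapse = " "), "\n",
      "axis mins: ", paste(format(volume$origin, digits = 17), collapse = " "), "\n",
      "endian: little\n",
      "encoding: raw\n\n")
    con <- file(path, "wb")
    writeChar(header, con, eos = NULL)
    writeBin(vals, con, size = 8, endian = "little")
    close(con)
  } else {
    img <- RNifti::asNifti(array(vals, dims))
    RNifti::pixdim(img) <- volume$spacing
    # LPS -> RAS: flip the sign of the x and y axes in the stored transform
    m <- diag(c(-volume$spacing[1], -volume$spacing[2], volume$spacing[3], 1))
    m[1:3, 4] <- c(-volume$origin[1], -volume$origin[2], volume$origin[3])
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

parse_kv_header <- function(lines, sep) {
  kv <- regmatches(lines, regexpr(sep, lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1)))
  names(vals) <- tolower(keys)
  vals
}

read_raw_block <- function(con, n, type, endian) {
  switch(type,
         double = readBin(con, "double", n, size = 8, endian = endian),
         float = readBin(con, "double", n, size = 4, endian = endian),
         short = readBin(con, "integer", n, size = 2, endian = endian),
         ushort = readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian),
         uchar = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
         stop("unsupported element type: ", type))
}

#' Read a volume from disk
#'
#' Counterpart of [write_volume()]; the round trip preserves values
#' bit-exactly and spacing/origin to at least 1e-6 mm.
#'
#' @param path file path (.mha/.mhd, .nrrd, .nii/.nii.gz).
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- volume_format(path)
  if (fmt %in% c("mha", "mhd")) {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    lines <- character(0)
    repeat {
      l <- readLines(con, n = 1, warn = FALSE)
      if (length(l) == 0) stop("malformed MetaImage header: no ElementDataFile")
      lines <- c(lines, l)
      if (grepl("^\\s*ElementDataFile", l)) break
    }
    h <- parse_kv_header(lines, "=")
    dims <- as.integer(strsplit(h[["dimsize"]], "\\s+")[[1]])
    spacing <- as.numeric(strsplit(h[["elementspacing"]], "\\s+")[[1]])
    origin <- if (!is.na(h["offset"]))
      as.numeric(strsplit(h[["offset"]], "\\s+")[[1]]) else rep(0, 3)
    type <- switch(h[["elementtype"]],
                   MET_DOUBLE = "double", MET_FLOAT = "float",
                   MET_SHORT = "short", MET_USHORT = "ushort",
                   MET_UCHAR = "uchar",
                   stop("unsupported MetaImage element type: ", h[["elementtype"]]))
    endian <- if (identical(tolower(h["binarydatabyteordermsb"]), "true"))
      "big" else "little"
    datafile <- h[["elementdatafile"]]
    if (identical(datafile, "LOCAL")) {
      vals <- read_raw_block(con, prod(dims), type, endian)
    } else {
      rawcon <- file(file.path(dirname(path), datafile), "rb")
      on.exit(close(rawcon), add = TRUE)
      vals <- read_raw_block(rawcon, prod(dims), type, endian)
    }
  } else if (fmt == "nrrd") {
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    magic <- readLines(con, n = 1, warn = FALSE)
    if (!grepl("^NRRD", magic)) stop("malformed NRRD header: bad magic")
    lines <- character(0)
    repeat {
      l <- readLines(con, n = 1, warn = FALSE)
      if (length(l) == 0) stop("malformed NRRD header: missing blank line")
      if (nchar(trimws(l)) == 0) break
      if (!grepl("^#", l)) lines <- c(lines, l)
    }
    h <- parse_kv_header(lines, ": ")
    if (!identical(h[["encoding"]], "raw"))
      stop("unsupported NRRD encoding: ", h[["encoding"]])
    dims <- as.integer(strsplit(h[["sizes"]], "\\s+")[[1]])
    spacing <- if (!is.na(h["spacings"]))
      as.numeric(strsplit(h[["spacings"]], "\\s+")[[1]]) else rep(1, 3)
    origin <- if (!is.na(h["axis mins"]))
      as.numeric(strsplit(h[["axis mins"]], "\\s+")[[1]])
    else -(dims - 1) / 2 * spacing
    type <- switch(h[["type"]],
                   double = "double", float = "float", short = "short",
                   `unsigned short` = "ushort", uchar = "uchar",
                   stop("unsupported NRRD type: ", h[["type"]]))
    endian <- if (identical(h["endian"], c(endian = "big"))) "big" else "little"
    vals <- read_raw_block(con, prod(dims), type, endian)
  } else {
    img <- RNifti::readNifti(path)
    dims <- dim(img)
    if (length(dims) != 3) stop("expected a 3D NIfTI volume")
    m <- RNifti::xform(img)
    R <- m[1:3, 1:3]
    if (max(abs(R - diag(diag(R)))) > 1e-6)
      stop("oblique NIfTI orientations are not supported")
    if (any(diag(R)[1:2] > 0) || diag(R)[3] < 0)
      stop("unsupported NIfTI axis orientation (expected LPS-compatible)")
    spacing <- abs(diag(R))
    origin <- c(-m[1, 4], -m[2, 4], m[3, 4])  # RAS -> LPS
    vals <- as.numeric(img)
  }
  if (length(vals) < prod(dims)) stop("malformed volume: truncated data block")
  voxel_volume(array(vals, dims), spacing, origin)
}

#' Write a radiograph with its JSON sidecar
#'
#' Pixel data are quantized to 16 bits with the float scale/offset stored in
#' a mandatory sidecar (`<path>.json`) together with domain, projection
#' geometry and pixel pitch, giving a round-trip error of at most 1 part in
#' 2^16 - 1 of the dynamic range. PNG reading requires the `png` package.
#'
#' @param rad a [radiograph()] or `pibs_image`.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(rad, path) {
  low <- tolower(path)
  rng <- range(rad$values)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  norm <- (rad$values - rng[1]) / scale
  norm <- round(norm * 65535) / 65535   # the stored 16-bit quantization
  if (grepl("\\.tiff?$", low)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16L, compression = "none")
  } else if (grepl("\\.png$", low)) {
    write_png16(norm, path)
  } else stop("unsupported radiograph format: ", basename(path),
              " (expected .tiff or .png)")
  g <- rad$geometry
  side <- list(domain = rad$domain, pitch_mm = rad$pitch_mm,
               difference = inherits(rad, "pibs_image"),
               offset = rng[1], scale = scale,
               geometry = list(gantry_deg = g$gantry_deg, sad_mm = g$sad_mm,
                               sid_mm = g$sid_mm, det_rows = g$det_rows,
                               det_cols = g$det_cols,
                               det_pitch_mm = g$det_pitch_mm,
                               isocenter = g$isocenter))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# table-driven CRC-32 (PNG/zlib polynomial) over a raw vector
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8)
          c <- if (bitwAnd(c, 1L) == 1L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(tab[idx + 1], bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

int32_bytes <- function(x) {
  x <- as.double(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int32_bytes(length(data)), body,
    int32_bytes(as.double(crc32(body)) %% 2^32))
}

# minimal 16-bit grayscale PNG writer (the png package writes 8-bit only)
write_png16 <- function(norm, path) {
  h <- nrow(norm); w <- ncol(norm)
  q <- round(pmin(pmax(norm, 0), 1) * 65535)
  # scanlines: filter byte 0 + big-endian 16-bit samples, rows top-down
  qt <- t(q)  # column j = image row j, left to right
  pix <- as.raw(as.vector(rbind(as.vector(qt) %/% 256, as.vector(qt) %% 256)))
  dim(pix) <- c(2L * w, h)
  scan <- matrix(as.raw(0), 1L + 2L * w, h)  # leading filter byte 0 per row
  scan[-1, ] <- pix
  ihdr <- c(int32_bytes(w), int32_bytes(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale
  idat <- memCompress(as.raw(scan), type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a radiograph written by [write_radiograph()]
#' @param path image path; `<path>.json` must exist.
#' @return A [radiograph()].
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for radiograph: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  low <- tolower(path)
  norm <- if (grepl("\\.tiff?$", low)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", low)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG radiographs")
    png::readPNG(path)
  } else stop("unsupported radiograph format: ", basename(path))
  vals <- norm * side$scale + side$offset
  gg <- side$geometry
  geom <- projection_geometry(gg$gantry_deg, gg$sad_mm, gg$sid_mm,
                              gg$det_rows, gg$det_cols, gg$det_pitch_mm,
                              unlist(gg$isocenter))
  if (isTRUE(side$difference)) {
    # difference images keep negative values; bypass domain validation
    return(structure(list(values = vals, domain = side$domain,
                          pitch_mm = side$pitch_mm, geometry = geom,
                          provenance = list(domain = side$domain,
                                            additive = side$domain == "line_integral",
                                            gantry_deg = geom$gantry_deg)),
                     class = c("pibs_image", "radiograph")))
  }
  if (side$domain == "intensity") vals <- pmin(pmax(vals, 1e-12), 1)
  if (side$domain == "line_integral") vals <- pmax(vals, 0)
  radiograph(vals, side$domain, geom)
}

#' Serialize an evaluation report
#'
#' Writes the report tables as flat CSV files plus one JSON file holding
#' everything, into `dir`.
#'
#' @param report a `pibs_report` from [evaluation_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("contrast", "cnr_ratio", "motion", "motion_conventional",
               "registration")) {
    tab <- report[[nm]]
    if (!is.null(tab))
      utils::write.csv(as.data.frame(tab), file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(lapply(unclass(report), function(x)
    if (is.null(x)) NULL else as.data.frame(x)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a serialized evaluation report
#' @param dir directory written by [write_report()].
#' @return A `pibs_report` with the same tables.
#' @export
read_report <- function(dir) {
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  out <- lapply(js, function(x) if (is.null(x)) NULL else tibble::as_tibble(x))
  structure(out, class = "pibs_report")
}
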