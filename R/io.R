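## File I/O. Includes a minimal baseline TIFF codec (single channel,
## uncompressed, little-endian; 8/16-bit unsigned integer or 32-bit float)
## because no TIFF package is available in the target stack. Values are
## preserved exactly for integer data; no rescaling ever happens.

.TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.readUint <- function(con, size, endian) {
  v <- readBin(con, "integer", n = 1L, size = size, signed = size == 4L,
               endian = endian)
  if (size == 4L && v < 0) v <- v + 2^32
  v
}

#' Write a single-channel TIFF
#'
#' Uncompressed, little-endian, single-strip greyscale TIFF. The sample
#' format is chosen from the data unless forced: whole numbers in [0, 255]
#' are stored as 8-bit, in [0, 65535] as 16-bit, anything else as 32-bit
#' IEEE float. The physical pixel size is stored in the resolution tags
#' (pixels per centimetre) and recovered on read.
#'
#' @param image an [IntensityImage-class] or numeric matrix.
#' @param path output file path.
#' @param pixelSizeUm pixel size when \code{image} is a plain matrix.
#' @param format \code{"auto"} (default), \code{"uint8"}, \code{"uint16"}
#'   or \code{"float32"}.
#' @return \code{path}, invisibly.
#' @seealso [readTiff()], [readIntensityImage()]
#' @export
writeTiff <- function(image, path, pixelSizeUm = NULL,
                      format = c("auto", "uint8", "uint16", "float32")) {
  format <- match.arg(format)
  if (is(image, "IntensityImage")) {
    px <- image@pixels
    if (is.null(pixelSizeUm)) pixelSizeUm <- image@pixelSizeUm
  } else {
    px <- image
    if (is.null(pixelSizeUm)) pixelSizeUm <- 1
  }
  stopifnot(is.matrix(px), all(is.finite(px)))
  h <- nrow(px); w <- ncol(px)
  isWhole <- all(px == round(px))
  if (format == "auto") {
    format <- if (isWhole && min(px) >= 0 && max(px) <= 255) "uint8"
      else if (isWhole && min(px) >= 0 && max(px) <= 65535) "uint16"
      else "float32"
  }
  if (format %in% c("uint8", "uint16")) {
    lim <- if (format == "uint8") 255 else 65535
    if (!isWhole || min(px) < 0 || max(px) > lim)
      stop("data do not fit ", format, " without loss; use float32")
  }
  bits <- switch(format, uint8 = 8L, uint16 = 16L, float32 = 32L)
  sampleFormat <- if (format == "float32") 3L else 1L
  vals <- as.vector(t(px))             # TIFF strips are row-major
  nbytes <- length(vals) * bits / 8L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  dataOffset <- 8L
  ifdOffset <- dataOffset + nbytes
  writeBin(as.integer(ifdOffset), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(vals, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(vals), con, size = bits / 8L, endian = "little")
  }
  # IFD: 13 entries + two RATIONAL values appended after it
  nEntries <- 13L
  ratOffset1 <- ifdOffset + 2L + nEntries * 12L + 4L
  ratOffset2 <- ratOffset1 + 8L
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {                   # SHORT: low 2 bytes + padding
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(nEntries, con, size = 2, endian = "little")
  entry(256, 4, 1, w)                   # ImageWidth
  entry(257, 4, 1, h)                   # ImageLength
  entry(258, 3, 1, bits)                # BitsPerSample
  entry(259, 3, 1, 1)                   # Compression = none
  entry(262, 3, 1, 1)                   # Photometric = BlackIsZero
  entry(273, 4, 1, dataOffset)          # StripOffsets
  entry(277, 3, 1, 1)                   # SamplesPerPixel
  entry(278, 4, 1, h)                   # RowsPerStrip (one strip)
  entry(279, 4, 1, nbytes)              # StripByteCounts
  entry(282, 5, 1, ratOffset1)          # XResolution
  entry(283, 5, 1, ratOffset2)          # YResolution
  entry(296, 3, 1, 3)                   # ResolutionUnit = cm
  entry(339, 3, 1, sampleFormat)        # SampleFormat
  writeBin(0L, con, size = 4, endian = "little")   # no next IFD
  # resolution = pixels per cm = 10000 / pixelSizeUm, as num/denom
  den <- 10000L
  num <- as.integer(round(10000 / pixelSizeUm * den))
  writeBin(c(num, den, num, den), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a single-channel TIFF
#'
#' Reads uncompressed greyscale TIFFs (8/16-bit unsigned integer or 32-bit
#' float, either byte order, one or many strips). Integer values are
#' preserved exactly — no rescaling. Multi-channel files and stacks are
#' rejected with a typed error naming the problem.
#'
#' @param path file path.
#' @return list: \code{pixels} (numeric matrix), \code{pixelSizeUm}
#'   (NA when the file has no resolution tags).
#' @export
readTiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  endian <- if (magic == "II") "little" else if (magic == "MM") "big"
    else stop("not a TIFF file (bad byte-order mark): ", path)
  if (.readUint(con, 2, endian) != 42L) stop("not a TIFF file: ", path)
  ifdOffset <- .readUint(con, 4, endian)
  seek(con, ifdOffset)
  n <- .readUint(con, 2, endian)
  tags <- list()
  for (i in seq_len(n)) {
    tag <- .readUint(con, 2, endian)
    type <- .readUint(con, 2, endian)
    count <- .readUint(con, 4, endian)
    valueField <- readBin(con, "raw", 4L)
    tags[[as.character(tag)]] <- list(type = type, count = count,
                                      raw = valueField)
  }
  nextIfd <- .readUint(con, 4, endian)
  if (nextIfd != 0L)
    stop("multi-page TIFF (image stack) not supported: ", path)

  parseVal <- function(entry) {
    if (is.null(entry)) return(NULL)
    size <- .TIFF_TYPE_SIZES[as.character(entry$type)]
    total <- size * entry$count
    getInts <- function(raw) {
      rcon <- rawConnection(raw)
      on.exit(close(rcon))
      if (entry$type == 5L) {             # RATIONAL: num/den pairs
        v <- readBin(rcon, "integer", n = 2L * entry$count, size = 4,
                     endian = endian)
        v <- ifelse(v < 0, v + 2^32, v)
        v[seq(1, length(v), 2)] / v[seq(2, length(v), 2)]
      } else {
        v <- readBin(rcon, "integer", n = entry$count, size = size,
                     signed = size == 4L, endian = endian)
        ifelse(v < 0 & size == 4L, v + 2^32, v)
      }
    }
    if (total <= 4L) {
      getInts(entry$raw)
    } else {
      oc <- rawConnection(entry$raw)
      off <- readBin(oc, "integer", 1L, size = 4, endian = endian)
      close(oc)
      if (off < 0) off <- off + 2^32
      seek(con, off)
      getInts(readBin(con, "raw", total))
    }
  }
  need <- function(tag) {
    v <- parseVal(tags[[as.character(tag)]])
    if (is.null(v)) stop("TIFF missing required tag ", tag, ": ", path)
    v
  }
  w <- need(256); h <- need(257)
  bits <- parseVal(tags[["258"]]); if (is.null(bits)) bits <- 1L
  spp <- parseVal(tags[["277"]]); if (is.null(spp)) spp <- 1L
  if (spp != 1L || length(bits) > 1L)
    stop("multi-channel TIFF (", max(spp, length(bits)),
         " channels): only single-channel images are supported")
  comp <- parseVal(tags[["259"]]); if (is.null(comp)) comp <- 1L
  if (comp != 1L) stop("compressed TIFF (compression ", comp,
                       ") not supported")
  photo <- parseVal(tags[["262"]]); if (is.null(photo)) photo <- 1L
  if (!photo %in% c(0L, 1L))
    stop("unsupported photometric interpretation ", photo,
         " (RGB/palette images are not single-channel)")
  fmt <- parseVal(tags[["339"]]); if (is.null(fmt)) fmt <- 1L
  if (!((fmt == 1L && bits %in% c(8L, 16L)) || (fmt == 3L && bits == 32L)))
    stop("unsupported sample format: ", bits, "-bit, format code ", fmt)
  offsets <- need(273)
  counts <- need(279)
  if (length(offsets) != length(counts))
    stop("corrupt TIFF: strip offset/count mismatch")
  raw <- raw(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    raw <- c(raw, readBin(con, "raw", counts[i]))
  }
  npx <- w * h
  rcon <- rawConnection(raw)
  on.exit(close(rcon), add = TRUE)
  vals <- if (fmt == 3L) {
    readBin(rcon, "numeric", n = npx, size = 4, endian = endian)
  } else {
    as.numeric(readBin(rcon, "integer", n = npx, size = bits / 8L,
                       signed = FALSE, endian = endian))
  }
  if (length(vals) != npx) stop("corrupt TIFF: truncated pixel data")
  px <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  xres <- parseVal(tags[["282"]])
  unit <- parseVal(tags[["296"]]); if (is.null(unit)) unit <- 2L
  pixelSizeUm <- if (!is.null(xres) && xres > 0 && unit == 3L)
    10000 / xres else NA_real_
  list(pixels = px, pixelSizeUm = pixelSizeUm)
}

#' Read a TIFF as an IntensityImage
#'
#' @param path TIFF file path.
#' @param pixelSizeUm overrides the file's resolution tags (required when
#'   the file carries none).
#' @param channelLabel channel description (default "2845cm-1").
#' @return An [IntensityImage-class].
#' @export
readIntensityImage <- function(path, pixelSizeUm = NULL,
                               channelLabel = "2845cm-1") {
  t <- readTiff(path)
  ps <- if (!is.null(pixelSizeUm)) pixelSizeUm
    else if (!is.na(t$pixelSizeUm)) t$pixelSizeUm else 1
  IntensityImage(t$pixels, ps, channelLabel)
}

#' Write a records table as CSV
#'
#' Fixed column order, header always present, full float precision,
#' undefined values as empty cells (never the string "NA" or NaN), so a
#' written table round-trips unchanged through [readTable()].
#'
#' @param records data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTables <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (any(vapply(records, function(col) any(is.nan(col)), logical(1))))
    stop("NaN found: undefined values must be NA with a flag column")
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a CSV table written by [writeTables()]
#'
#' @param path CSV path.
#' @return data.frame; empty cells become NA.
#' @export
readTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run configuration from YAML
#'
#' The \code{pipeline} section mirrors [PipelineConfig-class] field names;
#' unknown keys anywhere are rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return list with elements \code{pipeline} ([PipelineConfig-class]),
#'   \code{simulate} ([ImageGenParams-class]), \code{seed}, \code{out}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowedTop <- c("pipeline", "simulate", "assay", "seed", "out",
                  "log_level")
  unknown <- setdiff(names(cfg), allowedTop)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  checkSection <- function(section, fun) {
    if (is.null(section)) return(fun())
    bad <- setdiff(names(section), names(formals(fun)))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(fun, section)
  }
  list(pipeline = checkSection(cfg$pipeline, pipelineConfig),
       simulate = checkSection(cfg$simulate, imageGenParams),
       assay = if (!is.null(cfg$assay))
         checkSection(cfg$assay, assayGenParams) else NULL,
       seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L,
       out = cfg$out,
       log_level = if (!is.null(cfg$log_level)) cfg$log_level else "info")
}

#' Write an end-to-end report to a directory
#'
#' Emits the per-value table, outlier log, group summary, post-hoc table
#' and test statistics as CSVs, a machine-readable JSON manifest with the
#' resolved configuration and hash, and a human-readable log. Reruns with
#' identical inputs produce byte-identical files.
#'
#' @param report an object from [endToEndReport()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "srsReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTables(report$values, file.path(dir, "values.csv"))
  writeTables(report$removed, file.path(dir, "outliers_removed.csv"))
  writeTables(report$groupSummary, file.path(dir, "group_summary.csv"))
  writeTables(report$test@postHoc, file.path(dir, "post_hoc.csv"))
  tt <- data.frame(test = report$test@testName,
                   statistic = paste(sprintf("%s=%.10g",
                     names(report$test@statistic), report$test@statistic),
                     collapse = ";"),
                   df = paste(report$test@df, collapse = ";"),
                   p = paste(signif(report$test@pValue, 10), collapse = ";"))
  writeTables(tt, file.path(dir, "test.csv"))
  jsonlite::write_json(report$provenance,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log <- c(
    sprintf("design: %s  metric: %s", report$provenance$design,
            report$provenance$metric),
    sprintf("config hash: %s", report$provenance$config_hash),
    sprintf("groups: %s", paste(report$groupSummary$group, collapse = ", ")),
    sprintf("outliers removed: %d", nrow(report$removed)),
    sprintf("p = %s", paste(signif(report$test@pValue, 6), collapse = ", ")))
  writeLines(log, file.path(dir, "report.log"))
  invisible(dir)
}

#' Write a QC overlay PNG
#'
#' Greyscale rendering of the image with the included-FOV window borders
#' burned in at the maximum intensity — a quick visual check of what the
#' confluence gate selected. Requires the \pkg{png} package.
#'
#' @param image an [IntensityImage-class].
#' @param summary a [PipelineSummary-class] for that image.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeOverlayPng <- function(image, summary, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for overlays")
  px <- image@pixels
  g <- (px - min(px)) / max(max(px) - min(px), .Machine$double.eps)
  w <- summary@config@windowPx
  inc <- summary@fovs[summary@fovs$included, , drop = FALSE]
  for (i in seq_len(nrow(inc))) {
    r <- inc$row0[i] + c(1L, w); cl <- inc$col0[i] + c(1L, w)
    g[r[1]:r[2], cl] <- 1
    g[r, cl[1]:cl[2]] <- 1
  }
  png::writePNG(g, path)
  invisible(path)
}
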