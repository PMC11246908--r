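# File formats.
#
# Images travel as PGM (8- or 16-bit) and as a minimal uncompressed DICOM
# dialect (Explicit VR Little Endian, MONOCHROME2) that honours PixelSpacing.
# Landmarks travel as LabelMe-style JSON (point shapes whose labels are the
# vertebral corner names) and as flat name,x,y CSV.  Coordinates are always
# pixel units in files; mm conversion happens only in the metrics.

#' Write a grayscale image as binary PGM
#' @param img numeric matrix in `[0, 1]` (or integer matrix when
#'   `raw_values = TRUE`).
#' @param path output path.
#' @param maxval 255 or 65535.
#' @param raw_values write `img` as stored integers instead of rescaling.
#' @export
write_pgm <- function(img, path, maxval = 65535L, raw_values = FALSE) {
  maxval <- as.integer(maxval)
  v <- if (raw_values) as.integer(t(img)) else
    as.integer(round(pmin(pmax(t(img), 0), 1) * maxval))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval), con,
            eos = NULL)
  size <- if (maxval > 255L) 2L else 1L
  writeBin(v, con, size = size, endian = "big")
  invisible(path)
}

#' Write a label mask (0 background, 1 lumbar, 2 sacrum) as 8-bit PGM
#' @param mask integer matrix.
#' @param path output path.
#' @export
write_mask_pgm <- function(mask, path) {
  write_pgm(mask, path, maxval = 255L, raw_values = TRUE)
}

#' Read a PGM image (P2 or P5)
#' @param path file path.
#' @param normalize divide by maxval to get `[0, 1]` intensities.
#' @return numeric (or integer when `normalize = FALSE`) matrix.
#' @export
read_pgm <- function(path, normalize = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header: magic, width, height, maxval, separated by whitespace/comments
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) abort_data("truncated PGM header: %s", path)
    if (ch == "#") {
      while (length(c2 <- readChar(con, 1, useBytes = TRUE)) &&
             c2 != "\n") NULL
    } else if (grepl("[[:space:]]", ch)) {
      NULL
    } else {
      word <- ch
      repeat {
        c2 <- readChar(con, 1, useBytes = TRUE)
        if (length(c2) == 0 || grepl("[[:space:]]", c2)) break
        word <- paste0(word, c2)
      }
      tok <- c(tok, word)
    }
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.integer(tok[4])
  n <- w * h
  v <- if (magic == "P5") {
    readBin(con, "integer", n, size = if (maxval > 255L) 2L else 1L,
            signed = FALSE, endian = "big")
  } else if (magic == "P2") {
    as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  } else {
    abort_data("not a PGM file: %s", path)
  }
  if (length(v) < n) abort_data("truncated PGM data: %s", path)
  m <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
  if (normalize) m / maxval else m
}

#' Read a mask PGM as an integer label matrix
#' @param path file path.
#' @return integer matrix with the stored label values.
#' @export
read_mask_pgm <- function(path) {
  m <- read_pgm(path, normalize = FALSE)
  storage.mode(m) <- "integer"
  m
}

## ---- LabelMe-style JSON ----------------------------------------------------

LANDMARK_NAME_RE <- "^(L[1-5]|S1)(S|I)(A|P)$"

#' Write landmarks as LabelMe-style JSON
#' @param kps a [keypoint_set()].
#' @param path output path.
#' @param image_path,image_size optional provenance fields `(rows, cols)`.
#' @export
write_labelme <- function(kps, path, image_path = "", image_size = c(0, 0)) {
  shapes <- lapply(rownames(kps$points), function(nm) {
    list(label = nm,
         points = list(as.numeric(kps$points[nm, ])),
         group_id = NULL, shape_type = "point", flags = c())
  })
  obj <- list(
    version = "5.0.0",
    flags = list(anterior_side = kps$anterior_side),
    shapes = shapes,
    imagePath = image_path,
    imageHeight = as.integer(image_size[1]),
    imageWidth = as.integer(image_size[2])
  )
  if (!is.null(kps$pixel_spacing)) obj$pixelSpacing <- kps$pixel_spacing
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read landmarks from LabelMe-style JSON
#'
#' Point shapes whose labels are vertebral corner names become the landmark
#' set; other labels are skipped with a message.  A duplicated landmark
#' label is an error.
#' @param path file path.
#' @return a [keypoint_set()].
#' @export
read_labelme <- function(path) {
  obj <- jsonlite::read_json(path)
  pts <- list()
  for (sh in obj$shapes) {
    if (!identical(sh$shape_type, "point")) next
    lab <- sh$label
    if (!grepl(LANDMARK_NAME_RE, lab)) {
      message("read_labelme: skipping unknown label '", lab, "'")
      next
    }
    if (lab %in% names(pts)) {
      abort_data("duplicate landmark label '%s' in %s", lab, path)
    }
    pts[[lab]] <- as.numeric(unlist(sh$points[[1]]))
  }
  if (length(pts) == 0) abort_data("no landmark points in %s", path)
  side <- obj$flags$anterior_side
  if (is.null(side)) side <- "left"
  spacing <- if (is.null(obj$pixelSpacing)) NULL else
    as.numeric(unlist(obj$pixelSpacing))
  keypoint_set(pts, anterior_side = side, pixel_spacing = spacing)
}

#' Write landmarks as flat CSV (name,x,y)
#' @param kps a [keypoint_set()].
#' @param path output path.
#' @export
write_keypoints_csv <- function(kps, path) {
  df <- data.frame(name = rownames(kps$points),
                   x = kps$points[, "x"], y = kps$points[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read landmarks from flat CSV (name,x,y)
#' @param path file path.
#' @param anterior_side,pixel_spacing metadata not carried by the CSV.
#' @return a [keypoint_set()].
#' @export
read_keypoints_csv <- function(path, anterior_side = "left",
                               pixel_spacing = NULL) {
  df <- utils::read.csv(path)
  m <- cbind(x = df$x, y = df$y)
  rownames(m) <- df$name
  keypoint_set(m, anterior_side = anterior_side,
               pixel_spacing = pixel_spacing)
}

#' Write a parameter set as CSV or JSON
#'
#' Column order is fixed: LL, SHA, ISA_L4L5, ISA_L5S1, PLS_L4L5, PLS_L5S1.
#' @param params a `parameter_set` (or named vector over those names).
#' @param path output path; format chosen by extension (.csv or .json).
#' @export
write_parameters <- function(params, path) {
  v <- unclass(params)[PARAMETER_NAMES]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(v), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(as.list(v)), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a parameter set written by [write_parameters()]
#' @param path file path (.csv or .json).
#' @return a `parameter_set`.
#' @export
read_parameters <- function(path) {
  v <- if (grepl("\\.json$", path)) {
    unlist(jsonlite::read_json(path))
  } else {
    unlist(utils::read.csv(path)[1, ])
  }
  do.call(parameter_set, as.list(v[PARAMETER_NAMES]))
}

## ---- minimal DICOM ---------------------------------------------------------

dicom_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2 == 1) {
    value_raw <- c(value_raw, as.raw(if (vr %in% c("OB", "UI")) 0 else 0x20))
    len <- len + 1
  }
  head <- c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(as.integer(len), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

#' Write a grayscale image as minimal uncompressed DICOM
#'
#' Explicit VR Little Endian, MONOCHROME2, 16 bits, with PixelSpacing.
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @param pixel_spacing mm per pixel `(row, col)`.
#' @export
write_dicom <- function(img, path, pixel_spacing = c(1, 1)) {
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2)
  px <- as.integer(round(pmin(pmax(t(img), 0), 1) * 65535))
  us <- function(x) writeBin(as.integer(x), raw(), size = 2,
                             endian = "little")
  str_raw <- function(s) charToRaw(s)
  ts <- dicom_element(0x0002L, 0x0010L, "UI",
                      str_raw("1.2.840.10008.1.2.1"))
  meta_body <- ts
  meta_len <- dicom_element(0x0002L, 0x0000L, "UL",
                            writeBin(as.integer(length(meta_body)), raw(),
                                     size = 4, endian = "little"))
  ds <- c(
    dicom_element(0x0008L, 0x0060L, "CS", str_raw("DX")),
    dicom_element(0x0028L, 0x0002L, "US", us(1)),
    dicom_element(0x0028L, 0x0004L, "CS", str_raw("MONOCHROME2")),
    dicom_element(0x0028L, 0x0010L, "US", us(nrow(img))),
    dicom_element(0x0028L, 0x0011L, "US", us(ncol(img))),
    dicom_element(0x0028L, 0x0030L, "DS",
                  str_raw(sprintf("%g\\%g", pixel_spacing[1],
                                  pixel_spacing[2]))),
    dicom_element(0x0028L, 0x0100L, "US", us(16)),
    dicom_element(0x0028L, 0x0101L, "US", us(16)),
    dicom_element(0x0028L, 0x0102L, "US", us(15)),
    dicom_element(0x0028L, 0x0103L, "US", us(0)),
    dicom_element(0x7FE0L, 0x0010L, "OW",
                  writeBin(px, raw(), size = 2, endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta_len, meta_body, ds), con)
  invisible(path)
}

#' Read a minimal uncompressed DICOM file
#'
#' Supports Explicit VR Little Endian grayscale data as produced by
#' [write_dicom()] and by typical radiography exports.
#' @param path file path.
#' @return list with `image` (matrix in `[0, 1]`) and `pixel_spacing`.
#' @export
read_dicom <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 140 ||
      rawToChar(raw_all[129:132]) != "DICM") {
    abort_data("not a DICOM file: %s", path)
  }
  pos <- 133L
  u16 <- function(i) {
    as.integer(raw_all[i]) + 256L * as.integer(raw_all[i + 1L])
  }
  u32 <- function(i) {
    as.integer(raw_all[i]) + 256 * as.integer(raw_all[i + 1L]) +
      65536 * as.integer(raw_all[i + 2L]) +
      16777216 * as.integer(raw_all[i + 3L])
  }
  fields <- list()
  n <- length(raw_all)
  while (pos + 8 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      body <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      body <- pos + 8L
    }
    key <- sprintf("%04x%04x", group, elem)
    val <- if (len > 0) raw_all[body:(body + len - 1L)] else raw()
    fields[[key]] <- list(vr = vr, val = val)
    pos <- body + len
  }
  need <- function(key, what) {
    if (is.null(fields[[key]])) abort_data("DICOM missing %s", what)
    fields[[key]]
  }
  rows <- u16_raw(need("00280010", "Rows")$val)
  cols <- u16_raw(need("00280011", "Columns")$val)
  bits <- if (is.null(fields[["00280100"]])) 16L else
    u16_raw(fields[["00280100"]]$val)
  spacing <- if (is.null(fields[["00280030"]])) NULL else
    as.numeric(strsplit(trimws(rawToChar(fields[["00280030"]]$val)),
                        "\\\\")[[1]])
  pxr <- need("7fe00010", "PixelData")$val
  size <- if (bits > 8) 2L else 1L
  v <- readBin(pxr, "integer", rows * cols, size = size, signed = FALSE,
               endian = "little")
  maxv <- 2^bits - 1
  list(image = matrix(v, nrow = rows, ncol = cols, byrow = TRUE) / maxv,
       pixel_spacing = spacing)
}

u16_raw <- function(r) as.integer(r[1]) + 256L * as.integer(r[2])

#' Read a radiograph from PGM or DICOM
#'
#' @param path image path (`.pgm`, `.dcm`/`.dicom`).
#' @param pixel_spacing override / fallback spacing, mm per pixel.
#' @param anterior_side `"left"`, `"right"`, or `NULL` to let the landmark
#'   stage infer it from the sacral slope.
#' @param require_spacing error when no spacing is available (needed for
#'   mm-based metrics).
#' @return a `radiograph_record`: id, image, pixel_spacing, anterior_side,
#'   provenance.
#' @export
read_image <- function(path, pixel_spacing = NULL, anterior_side = NULL,
                       require_spacing = FALSE) {
  if (!file.exists(path)) abort_data("cannot read image: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    img <- read_pgm(path)
    spacing <- pixel_spacing
  } else if (ext %in% c("dcm", "dicom")) {
    d <- read_dicom(path)
    img <- d$image
    spacing <- if (is.null(pixel_spacing)) d$pixel_spacing else pixel_spacing
  } else {
    abort_data("unsupported image format '%s' (PGM or DICOM expected)", ext)
  }
  if (require_spacing && is.null(spacing)) {
    abort_data("pixel spacing unavailable for %s; supply pixel_spacing",
               path)
  }
  structure(list(
    id = tools::file_path_sans_ext(basename(path)),
    image = img,
    pixel_spacing = if (is.null(spacing)) NULL else
      rep(as.numeric(spacing), length.out = 2),
    anterior_side = anterior_side,
    provenance = list(path = path, format = ext)
  ), class = "radiograph_record")
}
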