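# Labeled 2D raster masks (segmented scout images) and Cartesian pencil-beam
# path measurements through them.
#
# Label scheme: 0 = background/air, 1 = object (attenuating non-target
# tissue), 2 = target (scattering region), 3 = excluded (radiosensitive).
# Gray-value mapping in PGM/PNG files: 0, 85, 170, 255 -> labels 0..3.

MASK_LABELS <- 0:3
MASK_GRAYS <- c(0L, 85L, 170L, 255L)

#' Labeled mask container
#'
#' @param labels integer matrix with values in `{0, 1, 2, 3}` (background,
#'   object, target, excluded). Rows index the vertical image axis, columns
#'   the horizontal one.
#' @param pixel_size physical size of one (square) pixel, cm.
#' @param name free-text mask name.
#' @return an object of class `labeled_mask`.
#' @export
labeled_mask <- function(labels, pixel_size, name = "") {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  lab <- as.integer(labels)
  bad <- setdiff(unique(lab), MASK_LABELS)
  if (length(bad)) {
    stop(sprintf("unknown label value(s): %s (allowed: 0,1,2,3)",
                 paste(sort(bad), collapse = ", ")))
  }
  stopifnot(is.finite(pixel_size), pixel_size > 0)
  m <- matrix(lab, nrow = nrow(labels), ncol = ncol(labels))
  structure(list(labels = m, pixel_size = pixel_size, name = name),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x$labels) + 1L, nbins = 4L)
  cat(sprintf(
    "<labeled_mask> %d x %d px @ %g cm/px%s | bg %d, object %d, target %d, excluded %d\n",
    nrow(x$labels), ncol(x$labels), x$pixel_size,
    if (nzchar(x$name)) paste0(" (", x$name, ")") else "",
    tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

mask_format_from_path <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("pgm", "png", "csv")) {
    stop(sprintf("unsupported mask format '%s' (supported: pgm, png, csv)", ext))
  }
  ext
}

gray_to_label <- function(gray) {
  idx <- match(as.integer(round(gray)), MASK_GRAYS)
  if (anyNA(idx)) {
    bad <- sort(unique(as.integer(round(gray))[is.na(idx)]))
    stop(sprintf("unmapped gray value(s) in mask: %s (expected 0, 85, 170, 255)",
                 paste(bad, collapse = ", ")))
  }
  MASK_LABELS[idx]
}

read_pgm_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header tokens: magic, width, height, maxval (comments start with '#')
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch)) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic must be P2 or P5)")
  if (is.na(w) || is.na(h) || w < 1 || h < 1) stop("invalid PGM dimensions")
  if (maxval != 255L) stop("only 8-bit (maxval 255) PGM masks are supported")
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
    if (length(vals) < w * h) stop("truncated PGM pixel data")
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
    if (length(vals) < w * h) stop("truncated PGM pixel data")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm_matrix <- function(gray, path, ascii = TRUE) {
  h <- nrow(gray); w <- ncol(gray)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    apply_rows <- apply(gray, 1L, paste, collapse = " ")
    writeLines(apply_rows, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(t(gray)), con)
  }
  invisible(path)
}

#' Read a labeled mask from PGM, PNG or CSV
#'
#' PGM (P2/P5) and 8-bit grayscale PNG files use the fixed gray-value mapping
#' 0, 85, 170, 255 -> labels 0 (background), 1 (object), 2 (target),
#' 3 (excluded); any other gray value is an error naming the offending
#' values. CSV files hold the integer labels directly (comma-separated, no
#' header).
#'
#' @param path file path; format inferred from the extension unless `format`
#'   is given.
#' @param pixel_size physical pixel size, cm.
#' @param format one of `"pgm"`, `"png"`, `"csv"`.
#' @param name mask name (defaults to the file name).
#' @return a [labeled_mask()].
#' @export
read_mask <- function(path, pixel_size, format = NULL, name = basename(path)) {
  if (is.null(format)) format <- mask_format_from_path(path)
  labels <- switch(
    format,
    pgm = {
      g <- read_pgm_matrix(path)
      matrix(gray_to_label(g), nrow = nrow(g))
    },
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) {
        chans <- dim(img)[3]
        flat <- matrix(img, ncol = chans)
        if (chans >= 3 &&
            (max(abs(flat[, 1] - flat[, 2])) > 1e-9 ||
             max(abs(flat[, 1] - flat[, 3])) > 1e-9)) {
          stop("PNG mask must be grayscale")
        }
        img <- img[, , 1]
      }
      gray <- round(img * 255)
      matrix(gray_to_label(gray), nrow = nrow(gray))
    },
    csv = {
      dat <- utils::read.table(path, sep = ",", header = FALSE,
                               colClasses = "integer")
      as.matrix(dat)
    },
    stop(sprintf("unsupported mask format '%s'", format))
  )
  dimnames(labels) <- NULL
  labeled_mask(labels, pixel_size, name = name)
}

#' Write a labeled mask to PGM, PNG or CSV
#'
#' Inverse of [read_mask()]; a write/read cycle reproduces the labels
#' bit-exactly.
#'
#' @param mask a [labeled_mask()].
#' @param path output path; format inferred from the extension unless given.
#' @param format one of `"pgm"`, `"png"`, `"csv"`.
#' @param ascii for PGM, write plain-text P2 (default) rather than binary P5.
#' @export
write_mask <- function(mask, path, format = NULL, ascii = TRUE) {
  stopifnot(inherits(mask, "labeled_mask"))
  if (is.null(format)) format <- mask_format_from_path(path)
  gray <- matrix(MASK_GRAYS[mask$labels + 1L], nrow = nrow(mask$labels))
  switch(
    format,
    pgm = write_pgm_matrix(gray, path, ascii = ascii),
    png = png::writePNG(gray / 255, target = path),
    csv = utils::write.table(mask$labels, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    stop(sprintf("unsupported mask format '%s'", format))
  )
  invisible(path)
}

#' Measure one Cartesian pencil-beam path through a mask
#'
#' Traces a full grid row or column. The attenuation path length `l` counts
#' all in-object pixels (object + target, since both share the same linear
#' attenuation coefficient); set `include_target_in_path = FALSE` to count
#' object pixels only. The effective target radius is half the traversed
#' target extent, `r_t_eff = target_pixels * pixel_size / 2`.
#'
#' @param mask a [labeled_mask()].
#' @param orientation `"row"` or `"column"`.
#' @param index 1-based row/column index.
#' @param include_target_in_path count target pixels in `l` (default TRUE).
#' @return a one-row data.frame with columns `orientation`, `index`, `l`
#'   (cm), `r_t_eff` (cm), `target_pixels`, `object_pixels`,
#'   `intersects_excluded`.
#' @export
trace_axis_path <- function(mask, orientation = c("row", "column"), index,
                            include_target_in_path = TRUE) {
  stopifnot(inherits(mask, "labeled_mask"))
  orientation <- match.arg(orientation)
  nmax <- if (orientation == "row") nrow(mask$labels) else ncol(mask$labels)
  if (index < 1L || index > nmax) {
    stop(sprintf("%s index %d out of range [1, %d]", orientation, index, nmax))
  }
  line <- if (orientation == "row") mask$labels[index, ] else mask$labels[, index]
  target_px <- sum(line == 2L)
  object_px <- sum(line == 1L)
  attn_px <- object_px + if (include_target_in_path) target_px else 0L
  data.frame(
    orientation = orientation,
    index = as.integer(index),
    l = attn_px * mask$pixel_size,
    r_t_eff = target_px * mask$pixel_size / 2,
    target_pixels = target_px,
    object_pixels = object_px,
    intersects_excluded = any(line == 3L)
  )
}

#' Measure all Cartesian paths through a mask
#'
#' Traces every `stride`-th row and/or column (starting at index 1), in
#' deterministic order: rows ascending, then columns ascending.
#'
#' @param mask a [labeled_mask()].
#' @param orientations character vector, subset of `c("row", "column")`.
#' @param stride trace every `stride`-th line (>= 1).
#' @param include_target_in_path see [trace_axis_path()].
#' @return a data.frame of path measurements, one row per traced path.
#' @export
scan_paths <- function(mask, orientations = c("row", "column"), stride = 1L,
                       include_target_in_path = TRUE) {
  stopifnot(inherits(mask, "labeled_mask"), stride >= 1L)
  orientations <- match.arg(orientations, c("row", "column"), several.ok = TRUE)
  if (!length(orientations)) stop("orientations must not be empty")
  out <- list()
  if ("row" %in% orientations) {
    for (i in seq(1L, nrow(mask$labels), by = stride)) {
      out[[length(out) + 1L]] <-
        trace_axis_path(mask, "row", i, include_target_in_path)
    }
  }
  if ("column" %in% orientations) {
    for (j in seq(1L, ncol(mask$labels), by = stride)) {
      out[[length(out) + 1L]] <-
        trace_axis_path(mask, "column", j, include_target_in_path)
    }
  }
  do.call(rbind, out)
}
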