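# Image containers are plain base-R objects on a 0-255 intensity scale:
#   grayscale  -> numeric H x W matrix (row = image row)
#   RGB        -> numeric H x W x 3 array
#   binary     -> logical H x W matrix
# PNG is handled by the png package; PGM/PPM (both ASCII and raw) are
# implemented here since no pre-installed package reads them.

#' Read an image file
#'
#' Reads PNG, PGM or PPM (ASCII `P2`/`P3` or raw `P5`/`P6`) images and
#' returns intensities on a 0-255 scale: a `H x W` numeric matrix for
#' grayscale input or a `H x W x 3` array for color input.
#'
#' @param path Path to a `.png`, `.pgm` or `.ppm` file.
#' @return Numeric matrix (grayscale) or 3-d array (RGB).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path) * 255
    if (length(dim(a)) == 3 && dim(a)[3] >= 3) {
      return(a[, , 1:3, drop = FALSE])
    }
    if (length(dim(a)) == 3) a <- a[, , 1]
    return(a)
  }
  if (ext %in% c("pgm", "ppm", "pnm")) {
    return(read_pnm(path))
  }
  stop("unsupported image format '", ext, "' (supported: png, pgm, ppm)",
       call. = FALSE)
}

#' Write an image file
#'
#' Writes a grayscale matrix, logical mask or RGB array (0-255 scale) as
#' PNG, or as PGM/PPM when the path ends in `.pgm`/`.ppm`.
#'
#' @param img Numeric matrix, logical matrix, or `H x W x 3` array.
#' @param path Output path; the extension selects the format.
#' @param ascii For PNM output, write the ASCII (`P2`/`P3`) variant.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, ascii = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (is.logical(img)) {
    img <- img * 255
    if (is.null(dim(img))) dim(img) <- c(1L, length(img))
  }
  img <- pmin(pmax(img, 0), 255)
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext %in% c("pgm", "ppm", "pnm")) {
    write_pnm(img, path, ascii = ascii)
  } else {
    stop("unsupported output format '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

# -- PNM (portable anymap) ---------------------------------------------------

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("not a supported PNM file (magic '", magic, "'): ", path,
         call. = FALSE)
  }
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1 || h < 1) {
    stop("malformed PNM header in ", path, call. = FALSE)
  }
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.numeric(w) * h * nch
  if (magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval > 255) {
      raw2 <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                      endian = "big")
      vals <- raw2
    } else {
      vals <- as.integer(readBin(con, "raw", n = n))
    }
  }
  if (length(vals) != n) stop("truncated PNM data in ", path, call. = FALSE)
  vals <- vals * (255 / maxval)
  if (nch == 1L) {
    # PNM stores row-major
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      a[, , ch] <- matrix(vals[seq(ch, n, by = 3)], nrow = h, ncol = w,
                          byrow = TRUE)
    }
    a
  }
}

# Reads one whitespace-delimited token, skipping '#' comments.
read_pnm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste0(tok, collapse = "")
}

write_pnm <- function(img, path, ascii = FALSE) {
  vals <- round(pmin(pmax(img, 0), 255))
  rgb <- length(dim(vals)) == 3
  h <- dim(vals)[1]; w <- dim(vals)[2]
  if (rgb) {
    magic <- if (ascii) "P3" else "P6"
    # interleave channels row-major
    flat <- integer(h * w * 3)
    for (ch in 1:3) {
      flat[seq(ch, length(flat), by = 3)] <- as.integer(t(vals[, , ch]))
    }
  } else {
    magic <- if (ascii) "P2" else "P5"
    flat <- as.integer(t(vals))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(flat, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

# -- small shared helpers ----------------------------------------------------

# Coerce an argument that may be a path or an in-memory image.
as_image <- function(x) {
  if (is.character(x)) read_image(x) else x
}

# Any image-like input to a logical mask (>127 on the 0-255 scale).
as_mask <- function(x) {
  x <- as_image(x)
  if (length(dim(x)) == 3) x <- x[, , 1]
  if (is.logical(x)) x else x > 127
}

# Extract one channel of an RGB array (or pass a matrix through).
select_channel <- function(img, channel = c("green", "red", "blue", "gray")) {
  channel <- match.arg(channel)
  if (is.matrix(img)) return(img)
  idx <- switch(channel, red = 1L, green = 2L, blue = 3L, gray = NA_integer_)
  if (is.na(idx)) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img[, , idx]
  }
}

stopifnot_same_dim <- function(a, b, what) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("dimension mismatch: ", what, " is ",
         paste(dim(b)[1:2], collapse = "x"), " but image is ",
         paste(dim(a)[1:2], collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}
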