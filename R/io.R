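#' Write a float map as 32-bit TIFF with a JSON sidecar
#'
#' Stores `values / scale` as a 32-bit float TIFF (TIFF float storage is
#' defined on [0, 1]) and records the scale, units, mask and provenance in a
#' plain-text JSON sidecar `<path>.json`. NA/masked pixels are written as 0
#' and recorded in the sidecar mask summary.
#'
#' @param values Numeric matrix.
#' @param path Output TIFF path.
#' @param units Unit string recorded in the sidecar (e.g. `"kPa"`, `"mm"`,
#'   `"px"`).
#' @param valid Optional logical mask (written as a second TIFF page).
#' @param metadata Named list of extra sidecar fields.
#' @return `path`, invisibly.
#' @export
write_float_map <- function(values, path, units = "", valid = NULL,
                            metadata = list()) {
  finite <- is.finite(values)
  vmax <- if (any(finite)) max(abs(values[finite])) else 1
  scale <- if (vmax > 0) vmax else 1
  img <- values / scale
  img[!finite] <- 0
  img <- pmin(pmax(img, -1), 1)
  neg <- any(img < 0)
  if (neg) img <- (img + 1) / 2  # signed maps stored as (v/scale + 1) / 2
  pages <- list(img)
  if (!is.null(valid)) pages <- c(pages, list(matrix(as.numeric(valid),
                                                     nrow(values))))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(scale = scale, signed = neg, units = units,
                 dim = dim(values), n_valid = sum(finite),
                 package = "sopal",
                 version = as.character(utils::packageVersion("sopal"))),
            metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a float map written by [write_float_map()]
#'
#' @param path TIFF path (sidecar `<path>.json` must be present).
#' @return List `values`, `valid`, `units`, `metadata`.
#' @export
read_float_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- pages[[1]]
  if (isTRUE(side$signed)) img <- img * 2 - 1
  values <- img * side$scale
  valid <- if (length(pages) > 1) pages[[2]] > 0.5
           else matrix(TRUE, nrow(img), ncol(img))
  values[!valid] <- NA
  list(values = values, valid = valid, units = side$units, metadata = side)
}

#' Write a stereo pair to image files
#'
#' Either two separate grayscale PNGs or one side-by-side composite (the
#' probe streams both sensors merged side by side in a single frame).
#'
#' @param pair An [render_stereo_pair()] object.
#' @param path Output path; with `composite = TRUE` a single file, otherwise
#'   the stem used for `<path>_left.png` / `<path>_right.png`.
#' @param composite Write a single side-by-side frame.
#' @return Written path(s), invisibly.
#' @export
write_stereo_pair <- function(pair, path, composite = FALSE) {
  if (composite) {
    png::writePNG(cbind(pair$left, pair$right), path)
    return(invisible(path))
  }
  paths <- paste0(path, c("_left.png", "_right.png"))
  png::writePNG(pair$left, paths[1])
  png::writePNG(pair$right, paths[2])
  invisible(paths)
}

#' Read a stereo pair from image files
#'
#' @param left Left-image path, or the composite path when `right` is
#'   missing (the frame is split at its horizontal midpoint).
#' @param right Optional right-image path.
#' @param illumination_mode Recorded illumination tag.
#' @return An `sop_stereo_pair`.
#' @export
read_stereo_pair <- function(left, right = NULL, illumination_mode = "uv") {
  rd <- function(p) {
    img <- if (grepl("\\.tiff?$", p, ignore.case = TRUE)) tiff::readTIFF(p)
           else png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }
  if (is.null(right)) {
    comp <- rd(left)
    w <- ncol(comp) %/% 2L
    l <- comp[, seq_len(w)]
    r <- comp[, w + seq_len(w)]
  } else {
    l <- rd(left)
    r <- rd(right)
  }
  structure(list(left = l, right = r, illumination_mode = illumination_mode,
                 bit_depth = 8L),
            class = "sop_stereo_pair")
}

#' Write a plain-text key-value manifest
#'
#' @param meta Named list (vectors joined with spaces).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(meta, path) {
  lines <- vapply(names(meta), function(k)
    paste0(k, ": ", paste(format(meta[[k]], digits = 12), collapse = " ")),
    "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#'
#' @param path Manifest path.
#' @return Named list of character vectors.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  stats::setNames(lapply(kv, function(p) strsplit(p[2], " +")[[1]]),
                  vapply(kv, `[`, "", 1))
}
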