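#' Write an image stack to disk
#'
#' Writes either a multi-page TIFF (`path` ending in `.tif`/`.tiff`;
#' float32, lossless for simulated data) or a directory of numbered PNG
#' frames (16-bit). A YAML manifest carrying the generating camera and
#' acquisition metadata can be written alongside with
#' [write_stack_manifest()].
#'
#' @param stack An `image_stack` (or any list with a `frames` H x W x n
#'   array).
#' @param path Output `.tif`/`.tiff` file or directory (PNG frames).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  frames <- stack$frames
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    imgs <- lapply(seq_len(n), function(k) frames[, , k])
    tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_len(n)) {
      png::writePNG(pmin(pmax(frames[, , k], 0), 1),
                    file.path(path, sprintf("frame_%04d.png", k)))
    }
  }
  invisible(path)
}

#' Read an image stack from disk
#'
#' Accepts a multi-page TIFF or a directory of lexicographically ordered
#' PNG/TIFF frames. Integer images (8/16-bit) are normalized to `[0, 1]`
#' (65535 reads as 1.0); float32 data are passed through. Frame order is
#' preserved; inconsistent frame shapes are an error.
#'
#' @param path `.tif`/`.tiff` file or a frame directory.
#' @return An `image_stack` with `frames` (H x W x n array).
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    imgs <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)          # already in [0,1]
      } else {
        tiff::readTIFF(f)
      }
    })
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
  }
  imgs <- lapply(imgs, function(im) {
    if (length(dim(im)) == 3) im <- im[, , 1]   # first channel of color input
    im
  })
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent frame shapes in stack")
  }
  frames <- array(unlist(imgs), dim = c(dims[1, 1], dims[2, 1], length(imgs)))
  structure(list(frames = frames, n_frames = length(imgs),
                 camera_id = basename(path)),
            class = "image_stack")
}

#' Write / read a stack manifest (YAML)
#'
#' The manifest round-trips the acquisition metadata of a simulated
#' measurement: both cameras, the projector, the pattern seed and the noise
#' level, so a stack on disk is self-describing.
#'
#' @param manifest A list with entries among `cam1`, `cam2`
#'   ([telecentric_camera()]s), `projector` ([projector_model()]), `seed`,
#'   `noise_sigma`, `n_frames`.
#' @param path File path.
#' @return `read_stack_manifest()` returns the list with cameras and
#'   projector reconstructed; `write_...` returns `path` invisibly.
#' @export
write_stack_manifest <- function(manifest, path) {
  out <- manifest
  for (nm in c("cam1", "cam2")) {
    if (!is.null(out[[nm]])) out[[nm]] <- camera_to_list(out[[nm]])
  }
  if (!is.null(out$projector)) {
    p <- out$projector
    out$projector <- list(direction = as.numeric(p$direction),
                          up = as.numeric(p$up),
                          pattern_pitch = p$pattern_pitch)
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_stack_manifest
#' @export
read_stack_manifest <- function(path) {
  x <- yaml::read_yaml(path)
  for (nm in c("cam1", "cam2")) {
    if (!is.null(x[[nm]])) x[[nm]] <- camera_from_list(x[[nm]])
  }
  if (!is.null(x$projector)) {
    x$projector <- projector_model(as.numeric(x$projector$direction),
                                   as.numeric(x$projector$up),
                                   x$projector$pattern_pitch)
  }
  x
}
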