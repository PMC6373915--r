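#' Image stacks
#'
#' A stack is an ordered sequence of single-channel frames. Frames are plain
#' numeric matrices indexed `[row, col]` = `[y + 1, x + 1]`: the origin is
#' the top-left pixel, x runs rightward along columns, y downward along
#' rows, and pixel coordinates reported by the package are 0-based. Stacks
#' may be backed by in-memory matrices, by a multi-page TIFF on disk, or by
#' the synthetic renderer; frames are materialised one at a time so whole
#' movies never need to fit in memory.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @return an object of class `ngv_stack`.
#' @export
image_stack <- function(frames) {
  if (length(frames) == 0) stop("a stack needs at least one frame")
  dims <- lapply(frames, dim)
  if (length(unique(dims)) != 1)
    stop("all frames in a stack must share the same dimensions")
  new_stack(length(frames), dims[[1]],
            function(i) frames[[i]],
            source = "memory")
}

new_stack <- function(n, dim, get, source = "memory") {
  structure(list(n = as.integer(n), dim = as.integer(dim), get = get,
                 source = source),
            class = "ngv_stack")
}

#' Number of frames in a stack
#' @param x an `ngv_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.ngv_stack <- function(x) x$n

#' Extract one frame from a stack
#' @param x an `ngv_stack`.
#' @param i 1-based frame number.
#' @return a numeric matrix.
#' @export
get_frame <- function(x, i) UseMethod("get_frame")

#' @export
get_frame.ngv_stack <- function(x, i) {
  i <- as.integer(i)
  if (i < 1 || i > x$n) stop("frame index out of range: ", i)
  x$get(i)
}

#' @export
print.ngv_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d frame(s) of %dx%d px (%s-backed)\n",
              x$n, x$dim[1], x$dim[2], x$source))
  invisible(x)
}

## Lazily apply a per-frame transform (used for streaming preprocessing).
stack_map <- function(stack, f) {
  new_stack(stack$n, stack$dim, function(i) f(stack$get(i)),
            source = paste0(stack$source, "+map"))
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are taken in file order, one frame per page; 8- and 16-bit
#' grayscale are accepted and returned in native intensity units (0..255 or
#' 0..65535). Physical metadata (pixel size, frame interval) come from the
#' pipeline configuration, not from the file.
#'
#' @param path path to a TIFF file.
#' @param lazy if TRUE, frames are decoded on access rather than up front.
#' @return an `ngv_stack`.
#' @export
read_stack <- function(path, lazy = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE, all = TRUE),
                   error = function(e) stop("not a readable TIFF: ", path,
                                            " (", conditionMessage(e), ")"))
  n <- length(info$width)
  if (n == 0) stop("TIFF contains no pages: ", path)
  if (any(info$samples.per.pixel != 1))
    stop("page ", which(info$samples.per.pixel != 1)[1],
         " is not single-channel grayscale: ", path)
  if (length(unique(info$width)) != 1 || length(unique(info$length)) != 1)
    stop("inconsistent page shapes in ", path, " (page ",
         which(info$width != info$width[1] | info$length != info$length[1])[1],
         ")")
  bits <- info$bits.per.sample[1]
  scale <- 2^bits - 1
  decode <- function(i) {
    fr <- tiff::readTIFF(path, all = i)[[1]]
    if (!is.matrix(fr)) stop("page ", i, " of ", path, " is not grayscale")
    fr * scale
  }
  if (lazy)
    new_stack(n, c(info$length[1], info$width[1]), decode, source = "tiff")
  else
    image_stack(lapply(seq_len(n), decode))
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' @param stack an `ngv_stack` (or list of matrices) in intensity units.
#' @param path output file.
#' @param bits bits per sample (8 or 16); intensities are clipped to the
#'   representable range. The whole stack is materialised before writing
#'   (the TIFF writer has no append mode), so writing very long
#'   full-frame movies needs memory of order frames x pixels x 8 bytes.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  if (is.list(stack) && !inherits(stack, "ngv_stack"))
    stack <- image_stack(stack)
  scale <- 2^bits - 1
  frames <- lapply(seq_len(n_frames(stack)), function(i) {
    fr <- get_frame(stack, i)
    pmin(pmax(fr / scale, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bits, compression = "LZW")
  invisible(path)
}
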