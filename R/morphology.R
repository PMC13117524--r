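# Flat grayscale morphology over edge-replicated borders.
#
# All four operators are window extrema over the active cells of a flat
# structuring element. Border handling is edge replication so that constant
# images are fixed points everywhere, including the border, and the residual
# transforms are identically zero on constants.

# Edge-replicated pad of matrix m by r pixels on every side.
.padReplicate <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rep.int(1L, r), seq_len(h), rep.int(h, r))
  ci <- c(rep.int(1L, r), seq_len(w), rep.int(w, r))
  m[ri, ci, drop = FALSE]
}

.checkSeSize <- function(m, se) {
  s <- nrow(se@mask)
  if (s > 2L * min(dim(m)) + 1L)
    warning("structuring element much larger than the image; result is degenerate")
  invisible(s)
}

# Window extremum (op = pmax or pmin) over the active se offsets.
.morphExtremum <- function(m, se, op) {
  .checkSeSize(m, se)
  mask <- se@mask
  s <- nrow(mask)
  r <- (s - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  p <- .padReplicate(m, r)
  out <- NULL
  for (u in seq_len(s)) for (v in seq_len(s)) {
    if (!mask[u, v]) next
    blk <- p[(u - 1L) + seq_len(h), (v - 1L) + seq_len(w), drop = FALSE]
    out <- if (is.null(out)) blk else op(out, blk)
  }
  out
}

.dilateMat <- function(m, se) .morphExtremum(m, se, pmax)
.erodeMat  <- function(m, se) .morphExtremum(m, se, pmin)
.openMat   <- function(m, se) .dilateMat(.erodeMat(m, se), se)
.closeMat  <- function(m, se) .erodeMat(.dilateMat(m, se), se)

.wrapLike <- function(m, img) GrayImage(m, imageDomain(img))

#' Grayscale dilation
#'
#' Assigns to each pixel the maximum intensity over the structuring-element
#' neighborhood centered there (flat grayscale dilation). Borders are handled
#' by edge replication. Since the origin cell is always active, the output is
#' pointwise greater than or equal to the input.
#'
#' @param x a \linkS4class{GrayImage} or numeric matrix.
#' @param se a \linkS4class{StructuringElement}.
#' @return Same type as \code{x}.
#' @seealso \code{\link{erodeImage}}, \code{\link{morphResiduals}}
#' @export
setGeneric("dilateImage", function(x, se) standardGeneric("dilateImage"))

#' @rdname dilateImage
#' @export
setMethod("dilateImage", "GrayImage", function(x, se) .wrapLike(.dilateMat(x@pixels, se), x))

#' @rdname dilateImage
#' @export
setMethod("dilateImage", "matrix", function(x, se) .dilateMat(x, se))

#' Grayscale erosion
#'
#' Window minimum over the structuring-element neighborhood; the dual of
#' \code{\link{dilateImage}}. Output is pointwise less than or equal to the
#' input.
#'
#' @inheritParams dilateImage
#' @return Same type as \code{x}.
#' @export
setGeneric("erodeImage", function(x, se) standardGeneric("erodeImage"))

#' @rdname erodeImage
#' @export
setMethod("erodeImage", "GrayImage", function(x, se) .wrapLike(.erodeMat(x@pixels, se), x))

#' @rdname erodeImage
#' @export
setMethod("erodeImage", "matrix", function(x, se) .erodeMat(x, se))

#' Grayscale opening (erosion followed by dilation)
#'
#' Removes bright structures smaller than the structuring element; idempotent
#' and anti-extensive (output <= input).
#'
#' @inheritParams dilateImage
#' @return Same type as \code{x}.
#' @export
setGeneric("openImage", function(x, se) standardGeneric("openImage"))

#' @rdname openImage
#' @export
setMethod("openImage", "GrayImage", function(x, se) .wrapLike(.openMat(x@pixels, se), x))

#' @rdname openImage
#' @export
setMethod("openImage", "matrix", function(x, se) .openMat(x, se))

#' Grayscale closing (dilation followed by erosion)
#'
#' Fills dark structures smaller than the structuring element; idempotent and
#' extensive (output >= input).
#'
#' @inheritParams dilateImage
#' @return Same type as \code{x}.
#' @export
setGeneric("closeImage", function(x, se) standardGeneric("closeImage"))

#' @rdname closeImage
#' @export
setMethod("closeImage", "GrayImage", function(x, se) .wrapLike(.closeMat(x@pixels, se), x))

#' @rdname closeImage
#' @export
setMethod("closeImage", "matrix", function(x, se) .closeMat(x, se))

#' The four directional morphological residuals
#'
#' Computes the residual channels used as structural features, with the
#' subtraction oriented so every residual is non-negative:
#' \itemize{
#'   \item Ifd = dilation - image (external gradient)
#'   \item Ifc = closing - image (black top-hat)
#'   \item Ife = image - erosion (internal gradient)
#'   \item Ifo = image - opening (white top-hat)
#' }
#' Arithmetic is carried out in doubles, so there is no wraparound or
#' underflow for integer-domain images. All residuals are identically zero on
#' constant images, borders included.
#'
#' @param x a \linkS4class{GrayImage} or numeric matrix.
#' @param se a \linkS4class{StructuringElement}.
#' @return A \linkS4class{ResidualSet} (for GrayImage input) or a named list
#'   of matrices \code{ifd, ife, ifo, ifc} (for matrix input).
#' @export
#' @examples
#' se <- makeStructuringElement("square", 3)
#' m <- matrix(0, 3, 3); m[2, 2] <- 5
#' morphResiduals(m, se)$ifd   # 5 everywhere except 0 at the center
setGeneric("morphResiduals", function(x, se) standardGeneric("morphResiduals"))

.residualsMat <- function(m, se) {
  e <- .erodeMat(m, se)
  d <- .dilateMat(m, se)
  list(ifd = d - m,
       ife = m - e,
       ifo = m - .dilateMat(e, se),
       ifc = .erodeMat(d, se) - m)
}

#' @rdname morphResiduals
#' @export
setMethod("morphResiduals", "matrix", function(x, se) .residualsMat(x, se))

#' @rdname morphResiduals
#' @export
setMethod("morphResiduals", "GrayImage", function(x, se) {
  r <- .residualsMat(x@pixels, se)
  methods::new("ResidualSet",
               ifd = .wrapLike(r$ifd, x), ife = .wrapLike(r$ife, x),
               ifo = .wrapLike(r$ifo, x), ifc = .wrapLike(r$ifc, x))
})

#' Stack grayscale channels into a multi-channel image
#'
#' Concatenates equally sized single-channel images along a third dimension,
#' preserving the given order exactly (channel 1 is the first argument
#' element). This is the channel-fusion step that feeds the convolutional
#' models.
#'
#' @param channels list of \linkS4class{GrayImage}s or numeric matrices, all
#'   with identical dimensions (and domains, when GrayImages).
#' @return numeric array of dimension h x w x C with channel names taken from
#'   the list names when present.
#' @export
#' @examples
#' a <- matrix(1, 4, 4); b <- matrix(2, 4, 4)
#' dim(stackChannels(list(If = a, Ife = b)))
stackChannels <- function(channels) {
  if (!is.list(channels) || length(channels) < 1L)
    stop("channels must be a nonempty list")
  mats <- lapply(channels, function(ch) {
    if (methods::is(ch, "GrayImage")) ch@pixels else ch
  })
  d <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
    stop("all channels must share the same dimensions")
  doms <- vapply(channels, function(ch)
    if (methods::is(ch, "GrayImage")) ch@domain else NA_character_, "")
  if (length(unique(stats::na.omit(doms))) > 1L)
    stop("all channels must share the same intensity domain")
  arr <- array(unlist(mats, use.names = FALSE), dim = c(d, length(mats)))
  if (!is.null(names(channels))) dimnames(arr) <- list(NULL, NULL, names(channels))
  arr
}

#' Compute a named stack of model input channels from a grayscale image
#'
#' Maps a channel specification over \{If, Ifd, Ife, Ifo, Ifc\} to the
#' corresponding raw image / residual planes (uint8 scale); the rescale to
#' [0, 1] happens uniformly at model input. Residuals are computed once and
#' reused when several are requested. Repeating \code{"If"} implements the
#' channel-replication ablation.
#'
#' @param gray numeric matrix or \linkS4class{GrayImage} in the uint8 domain.
#' @param channels character vector over \code{c("If","Ifd","Ife","Ifo","Ifc")}.
#' @param se \linkS4class{StructuringElement} for the residual channels.
#' @return numeric array h x w x length(channels), dimnames on channel axis.
#' @export
morphChannels <- function(gray, channels, se = makeStructuringElement("disk", 7)) {
  m <- if (methods::is(gray, "GrayImage")) gray@pixels else gray
  ok <- c("If", "Ifd", "Ife", "Ifo", "Ifc")
  if (!all(channels %in% ok))
    stop("channels must be among: ", paste(ok, collapse = ", "))
  res <- NULL
  planes <- lapply(channels, function(ch) {
    if (ch == "If") return(m)
    if (is.null(res)) res <<- .residualsMat(m, se)
    res[[tolower(ch)]]
  })
  names(planes) <- channels
  stackChannels(planes)
}
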