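#' The seven expression classes
#'
#' Canonical ordered label set used throughout the package: confusion matrices,
#' softmax outputs and catalogs all follow this (alphabetical) order, and
#' prediction ties are broken toward the lowest index, i.e. toward "angry".
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' expressionClasses()
expressionClasses <- function() {
  c("angry", "disgust", "fear", "happy", "neutral", "sad", "surprise")
}

#' GrayImage: a 2-D intensity grid with a declared value domain
#'
#' Thin S4 wrapper around a numeric matrix carrying the intensity domain tag,
#' either \code{"uint8"} (values in [0, 255]) or \code{"unit"} (values in
#' [0, 1]). Rows index image rows (y), columns index image columns (x),
#' 0-based pixel coordinates in the maths, 1-based in R storage.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot domain \code{"uint8"} or \code{"unit"}.
#' @export
setClass("GrayImage", representation(pixels = "matrix", domain = "character"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must have height >= 1 and width >= 1")
  if (anyNA(p) || any(!is.finite(p))) return("pixel intensities must be finite")
  if (length(object@domain) != 1L || !object@domain %in% c("uint8", "unit"))
    return("domain must be 'uint8' or 'unit'")
  hi <- if (object@domain == "uint8") 255 else 1
  if (min(p) < 0 || max(p) > hi)
    return(sprintf("intensities outside declared domain [0, %s]", hi))
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities (rows = image rows).
#' @param domain intensity domain, \code{"uint8"} ([0,255]) or \code{"unit"}
#'   ([0,1]).
#' @return A \linkS4class{GrayImage}.
#' @export
#' @examples
#' img <- GrayImage(matrix(0:255, 16, 16), "uint8")
#' dim(img)
GrayImage <- function(pixels, domain = c("uint8", "unit")) {
  domain <- match.arg(domain)
  if (is.vector(pixels)) pixels <- matrix(pixels, nrow = 1L)
  storage.mode(pixels) <- "double"
  methods::new("GrayImage", pixels = pixels, domain = domain)
}

#' @describeIn GrayImage height and width of the image
#' @param x a GrayImage.
#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' Pixel matrix of a GrayImage
#' @param x a \linkS4class{GrayImage}.
#' @return numeric matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' Intensity domain tag of a GrayImage
#' @param x a \linkS4class{GrayImage}.
#' @return \code{"uint8"} or \code{"unit"}.
#' @export
setGeneric("imageDomain", function(x) standardGeneric("imageDomain"))

#' @rdname imageDomain
#' @export
setMethod("imageDomain", "GrayImage", function(x) x@domain)

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %dx%d [%s], intensity range [%g, %g]\n",
              d[1], d[2], object@domain,
              min(object@pixels), max(object@pixels)))
})

#' StructuringElement: flat (binary) morphological neighborhood mask
#'
#' Odd-sized square or Euclidean-disk binary mask with its origin at the
#' center cell. Flat elements define only spatial support: grayscale dilation
#' and erosion are the window maximum and minimum over the active cells. The
#' disk at half-width r = (s-1)/2 activates cell offsets (dx, dy) with
#' dx^2 + dy^2 <= r^2 (29 active cells at 7x7).
#'
#' @slot mask logical s x s matrix, s odd, center cell active.
#' @slot shape \code{"square"} or \code{"disk"}.
#' @export
setClass("StructuringElement", representation(mask = "matrix", shape = "character"))

setValidity("StructuringElement", function(object) {
  m <- object@mask
  s <- nrow(m)
  if (!is.logical(m)) return("mask must be logical")
  if (s != ncol(m)) return("mask must be square")
  if (s %% 2L == 0L) return("mask side must be odd")
  c0 <- (s + 1L) %/% 2L
  if (!m[c0, c0]) return("origin (center cell) must be active")
  if (!object@shape %in% c("square", "disk")) return("shape must be 'square' or 'disk'")
  TRUE
})

#' Construct a flat structuring element
#'
#' @param shape \code{"disk"} (Euclidean disk, the default used by the
#'   morphological residual channels) or \code{"square"}.
#' @param size odd positive side length in pixels; the default used throughout is 7.
#' @return A \linkS4class{StructuringElement}.
#' @export
#' @examples
#' sum(seMask(makeStructuringElement("disk", 7)))   # 29 active cells
#' sum(seMask(makeStructuringElement("square", 7))) # 49 active cells
makeStructuringElement <- function(shape = c("disk", "square"), size = 7L) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 1L || size %% 2L == 0L)
    stop("structuring element size must be an odd positive integer")
  r <- (size - 1L) %/% 2L
  if (shape == "square") {
    mask <- matrix(TRUE, size, size)
  } else {
    off <- seq_len(size) - r - 1L
    mask <- outer(off^2, off^2, "+") <= r^2
  }
  methods::new("StructuringElement", mask = mask, shape = shape)
}

#' Binary mask of a structuring element
#' @param x a \linkS4class{StructuringElement}.
#' @return logical matrix.
#' @export
setGeneric("seMask", function(x) standardGeneric("seMask"))

#' @rdname seMask
#' @export
setMethod("seMask", "StructuringElement", function(x) x@mask)

#' Shape tag of a structuring element
#' @param x a \linkS4class{StructuringElement}.
#' @export
setGeneric("seShape", function(x) standardGeneric("seShape"))

#' @rdname seShape
#' @export
setMethod("seShape", "StructuringElement", function(x) x@shape)

#' Side length of a structuring element
#' @param x a \linkS4class{StructuringElement}.
#' @export
setGeneric("seSize", function(x) standardGeneric("seSize"))

#' @rdname seSize
#' @export
setMethod("seSize", "StructuringElement", function(x) nrow(x@mask))

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement: %s %dx%d, %d active cells\n",
              object@shape, nrow(object@mask), ncol(object@mask),
              sum(object@mask)))
})

#' ResidualSet: the four directional morphological residuals
#'
#' Holds the external gradient (dilation - image), internal gradient
#' (image - erosion), white top-hat (image - opening) and black top-hat
#' (closing - image) of a source image. All four are pointwise non-negative
#' and share the source's dimensions and domain.
#'
#' @slot ifd \linkS4class{GrayImage}, dilation residual.
#' @slot ife \linkS4class{GrayImage}, erosion residual.
#' @slot ifo \linkS4class{GrayImage}, opening residual (white top-hat).
#' @slot ifc \linkS4class{GrayImage}, closing residual (black top-hat).
#' @export
setClass("ResidualSet",
         representation(ifd = "GrayImage", ife = "GrayImage",
                        ifo = "GrayImage", ifc = "GrayImage"))

setValidity("ResidualSet", function(object) {
  d <- dim(object@ifd@pixels)
  for (nm in c("ife", "ifo", "ifc")) {
    r <- methods::slot(object, nm)
    if (!identical(dim(r@pixels), d)) return("residuals must share dimensions")
  }
  for (nm in c("ifd", "ife", "ifo", "ifc"))
    if (min(methods::slot(object, nm)@pixels) < 0)
      return("residuals must be pointwise non-negative")
  TRUE
})

#' Extract one residual channel from a ResidualSet
#'
#' @param x a \linkS4class{ResidualSet}.
#' @param which one of \code{"Ifd"}, \code{"Ife"}, \code{"Ifo"}, \code{"Ifc"}
#'   (case-insensitive).
#' @return A \linkS4class{GrayImage}.
#' @export
setGeneric("residualChannel", function(x, which) standardGeneric("residualChannel"))

#' @rdname residualChannel
#' @export
setMethod("residualChannel", "ResidualSet", function(x, which) {
  nm <- tolower(which)
  if (!nm %in% c("ifd", "ife", "ifo", "ifc"))
    stop("unknown residual channel: ", which)
  methods::slot(x, nm)
})

setMethod("show", "ResidualSet", function(object) {
  d <- dim(object@ifd@pixels)
  cat(sprintf("ResidualSet %dx%d [%s]: Ifd, Ife, Ifo, Ifc\n",
              d[1], d[2], object@ifd@domain))
})

#' FaceCatalog: the labeled sample bookkeeping table
#'
#' One row per image sample with columns \code{path}, \code{subject_id},
#' \code{dataset} (source corpus tag) and \code{label} (one of the seven
#' expression classes). Subject identifiers are the unit of the
#' subject-independent protocol: every subject belongs to exactly one source.
#'
#' @slot records data.frame with the four columns above.
#' @export
setClass("FaceCatalog", representation(records = "data.frame"))

setValidity("FaceCatalog", function(object) {
  r <- object@records
  need <- c("path", "subject_id", "dataset", "label")
  if (!all(need %in% names(r))) return("records need columns path, subject_id, dataset, label")
  if (nrow(r) == 0L) return("catalog must contain at least one record")
  if (anyDuplicated(r$path)) return("duplicate image paths in catalog")
  if (any(!nzchar(r$subject_id))) return("subject_id must be nonempty")
  if (!all(r$label %in% expressionClasses()))
    return("labels must be among the seven expression classes")
  bySub <- tapply(r$dataset, r$subject_id, function(d) length(unique(d)))
  if (any(bySub > 1L)) return("each subject_id must map to a single dataset source")
  TRUE
})

#' Construct a FaceCatalog
#'
#' @param records data.frame with character columns \code{path},
#'   \code{subject_id}, \code{dataset}, \code{label}.
#' @return A \linkS4class{FaceCatalog}.
#' @export
FaceCatalog <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (nm in intersect(names(records), c("path", "subject_id", "dataset", "label")))
    records[[nm]] <- as.character(records[[nm]])
  rownames(records) <- NULL
  methods::new("FaceCatalog", records = records)
}

#' Records of a FaceCatalog
#' @param x a \linkS4class{FaceCatalog}.
#' @return data.frame.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "FaceCatalog", function(x) x@records)

#' Number of samples in a catalog
#' @param x a \linkS4class{FaceCatalog}.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "FaceCatalog", function(x) nrow(x@records))

#' Distinct subject identifiers in a catalog
#' @param x a \linkS4class{FaceCatalog}.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname subjectIds
#' @export
setMethod("subjectIds", "FaceCatalog", function(x) sort(unique(x@records$subject_id)))

#' Distinct dataset sources in a catalog
#' @param x a \linkS4class{FaceCatalog}.
#' @export
setGeneric("datasetSources", function(x) standardGeneric("datasetSources"))

#' @rdname datasetSources
#' @export
setMethod("datasetSources", "FaceCatalog", function(x) sort(unique(x@records$dataset)))

setMethod("show", "FaceCatalog", function(object) {
  r <- object@records
  cat(sprintf("FaceCatalog: %d samples, %d subjects, %d sources\n",
              nrow(r), length(unique(r$subject_id)), length(unique(r$dataset))))
  print(table(r$label))
})

#' FoldPlan: subject-level partition for k-fold cross-validation
#'
#' Subjects are shuffled with a seeded generator and dealt round-robin into k
#' pairwise-disjoint folds whose union is the full subject set.
#'
#' @slot folds list of k character vectors of subject_ids.
#' @slot seed integer seed that produced the shuffle.
#' @export
setClass("FoldPlan", representation(folds = "list", seed = "integer"))

setValidity("FoldPlan", function(object) {
  if (length(object@folds) < 2L) return("k must be >= 2")
  all_s <- unlist(object@folds)
  if (anyDuplicated(all_s)) return("folds must be pairwise disjoint")
  TRUE
})

#' Number of folds in a FoldPlan
#' @param x a \linkS4class{FoldPlan}.
#' @export
setGeneric("nFolds", function(x) standardGeneric("nFolds"))

#' @rdname nFolds
#' @export
setMethod("nFolds", "FoldPlan", function(x) length(x@folds))

#' Subjects of one fold
#' @param x a \linkS4class{FoldPlan}.
#' @param i fold index in 1..k.
#' @export
setGeneric("foldSubjects", function(x, i) standardGeneric("foldSubjects"))

#' @rdname foldSubjects
#' @export
setMethod("foldSubjects", "FoldPlan", function(x, i) {
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > length(x@folds)) stop("invalid fold index")
  x@folds[[i]]
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds, seed %d, fold sizes: %s\n",
              length(object@folds), object@seed,
              paste(vapply(object@folds, length, 1L), collapse = " ")))
})

#' ConfusionMatrix: true-by-predicted class counts
#'
#' Rows index the true class, columns the predicted class, both in the order
#' of \code{classNames}; diagonal entries are the per-class true positives.
#'
#' @slot counts non-negative integer N x N matrix.
#' @slot classNames ordered class labels.
#' @export
setClass("ConfusionMatrix",
         representation(counts = "matrix", classNames = "character"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  n <- length(object@classNames)
  if (nrow(m) != n || ncol(m) != n) return("counts must be N x N for N classes")
  if (any(m < 0) || any(m != round(m))) return("counts must be non-negative integers")
  TRUE
})

#' Count matrix of a ConfusionMatrix
#' @param x a \linkS4class{ConfusionMatrix}.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) {
  m <- x@counts
  dimnames(m) <- list(true = x@classNames, predicted = x@classNames)
  m
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix: %d classes, %d samples\n",
              length(object@classNames), sum(object@counts)))
  print(confusionCounts(object))
})

#' MorphNet: a morphology-fronted neural network model
#'
#' Holds the fixed (non-learnable) morphological channel specification and the
#' learnable network layers. The channel front-end maps a grayscale input to a
#' stack of channels drawn from \{If, Ifd, Ife, Ifo, Ifc\} with zero learnable
#' parameters; the layers are trained with Adam on softmax cross-entropy.
#'
#' @slot architecture identifier such as "MNN", "MCNN1", "MCNN2v5",
#'   "MOBILENETV2", "VGG19".
#' @slot channels ordered channel specification, e.g. c("If","Ife","Ifo").
#' @slot se \linkS4class{StructuringElement} used by the residual channels.
#' @slot inputSide canonical square input side in pixels.
#' @slot layers list of internal layer objects.
#' @slot trained logical.
#' @slot history per-epoch training history (empty before training).
#' @slot bestEpoch epoch whose weights are held (NA before training).
#' @export
setClass("MorphNet",
         representation(architecture = "character", channels = "character",
                        se = "StructuringElement", inputSide = "integer",
                        layers = "list", trained = "logical",
                        history = "data.frame", bestEpoch = "integer"))

setValidity("MorphNet", function(object) {
  if (length(object@channels) < 1L) return("at least one input channel")
  ok <- c("If", "Ifd", "Ife", "Ifo", "Ifc")
  if (!all(object@channels %in% ok))
    return("channels must be among If, Ifd, Ife, Ifo, Ifc")
  if (object@inputSide < nrow(object@se@mask))
    return("input side must be at least the structuring element size")
  TRUE
})

#' Ordered input channel specification of a model
#' @param x a \linkS4class{MorphNet}.
#' @export
setGeneric("modelChannels", function(x) standardGeneric("modelChannels"))

#' @rdname modelChannels
#' @export
setMethod("modelChannels", "MorphNet", function(x) x@channels)

#' Architecture identifier of a model
#' @param x a \linkS4class{MorphNet}.
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))

#' @rdname architecture
#' @export
setMethod("architecture", "MorphNet", function(x) x@architecture)

#' Per-epoch training history of a model
#' @param x a \linkS4class{MorphNet}.
#' @return data.frame with epoch, loss, accuracy, val_loss, val_accuracy.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "MorphNet", function(x) x@history)

setMethod("show", "MorphNet", function(object) {
  cat(sprintf("MorphNet <%s>: input %dx%d, channels [%s], se %s-%d\n",
              object@architecture, object@inputSide, object@inputSide,
              paste(object@channels, collapse = ","),
              object@se@shape, nrow(object@se@mask)))
  cat(sprintf("  learnable parameters: %s; trained: %s\n",
              format(countParameters(object), big.mark = ","), object@trained))
  if (object@trained && nrow(object@history))
    cat(sprintf("  best epoch %d, val accuracy %.4f\n", object@bestEpoch,
                max(object@history$val_accuracy)))
})
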