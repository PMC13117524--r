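# Model builders: the dense-only morphological baseline (MNN), the custom
# four-residual-channel CNN (MCNN1), the six three-channel MCNN2 variants on
# a depthwise-separable backbone, and backbone baseline adapters.

.newMorphNet <- function(architecture, channels, se, inputSide, layers) {
  methods::new("MorphNet", architecture = architecture, channels = channels,
               se = se, inputSide = as.integer(inputSide), layers = layers,
               trained = FALSE, history = data.frame(), bestEpoch = NA_integer_)
}

#' Channel specification of an MCNN2 variant
#'
#' The fixed variant table: channel 1 is always the raw grayscale image If,
#' channels 2-3 are a pair of morphological residuals.
#' v1 = (If, Ifd, Ife), v2 = (If, Ifd, Ifc), v3 = (If, Ifd, Ifo),
#' v4 = (If, Ife, Ifc), v5 = (If, Ife, Ifo), v6 = (If, Ifc, Ifo).
#'
#' @param variant one of "v1".."v6" (or "MCNN2v1".."MCNN2v6").
#' @return character vector of three channel names.
#' @export
mcnn2Channels <- function(variant) {
  v <- sub("^MCNN2", "", variant)
  tab <- list(v1 = c("If", "Ifd", "Ife"), v2 = c("If", "Ifd", "Ifc"),
              v3 = c("If", "Ifd", "Ifo"), v4 = c("If", "Ife", "Ifc"),
              v5 = c("If", "Ife", "Ifo"), v6 = c("If", "Ifc", "Ifo"))
  if (!v %in% names(tab)) stop("unknown MCNN2 variant: ", variant)
  tab[[v]]
}

#' Build the morphological-network (MNN) baseline
#'
#' A structure-only baseline with no convolutional feature extraction: a
#' fixed (non-learnable) opening with a 7x7 disk structuring element, a
#' subtraction stage producing the opening residual If - Io, a flatten layer
#' (160 x 160 = 25,600 values at the canonical side), a 512-unit ReLU hidden
#' dense layer and a 7-unit softmax output. Only the two dense layers carry
#' learnable parameters: 25,600 x 512 + 512 + 512 x 7 + 7 = 13,111,303 at the
#' canonical input side.
#'
#' @param inputSide square input side (default 160).
#' @param se structuring element for the opening (default 7x7 disk).
#' @param hiddenUnits hidden dense width (default 512).
#' @return A \linkS4class{MorphNet}.
#' @export
#' @examples
#' countParameters(buildMNN())  # 13111303
buildMNN <- function(inputSide = 160L, se = makeStructuringElement("disk", 7),
                     hiddenUnits = 512L) {
  flat <- as.integer(inputSide)^2
  layers <- list(.layerFlatten(),
                 .layerDense(flat, hiddenUnits), .layerReLU(),
                 .layerDense(hiddenUnits, 7L))
  .newMorphNet("MNN", "Ifo", se, inputSide, layers)
}

# Spatial side after nPools rounds of 2x2/stride-2 pooling (floor).
.sideAfterPools <- function(side, nPools) {
  for (i in seq_len(nPools)) side <- side %/% 2L
  side
}

#' Build the custom four-residual-channel CNN (MCNN1)
#'
#' Input = the four morphological residuals (Ifd, Ife, Ifo, Ifc) concatenated
#' into a 4-channel image (the morphological stage is fixed and contributes
#' zero learnable parameters), followed by four blocks of
#' [3x3 convolution, batch normalization, ReLU, 2x2 max-pool] with
#' 128/256/512/1024 filters, a flatten, a ReLU dense layer (default 16
#' units) and the 7-way softmax output.
#'
#' @param inputSide square input side (default 160).
#' @param se structuring element for the residuals (default 7x7 disk).
#' @param filters filter widths of the four blocks; scaled-down experiments
#'   use c(8, 16, 32, 64).
#' @param denseUnits hidden dense width (default 16).
#' @return A \linkS4class{MorphNet}.
#' @export
buildMCNN1 <- function(inputSide = 160L, se = makeStructuringElement("disk", 7),
                       filters = c(128L, 256L, 512L, 1024L), denseUnits = 16L) {
  stopifnot(length(filters) == 4L)
  channels <- c("Ifd", "Ife", "Ifo", "Ifc")
  layers <- list()
  inC <- length(channels)
  for (f in filters) {
    layers <- c(layers, list(.layerConv(inC, f), .layerBN(f),
                             .layerReLU(), .layerPool()))
    inC <- f
  }
  sOut <- .sideAfterPools(as.integer(inputSide), 4L)
  layers <- c(layers, list(.layerFlatten(),
                           .layerDense(sOut^2 * inC, denseUnits), .layerReLU(),
                           .layerDense(denseUnits, 7L)))
  .newMorphNet("MCNN1", channels, se, inputSide, layers)
}

# Depthwise-separable backbone: stem conv block then dw/pw blocks, global
# average pooling and a small dense head. Identical for every 3-channel
# input specification, so parameter counts match across MCNN2 variants and
# the channel-replication baseline by construction.
.dsBackboneLayers <- function(widths = c(16L, 32L, 64L, 128L), denseUnits = 16L) {
  layers <- list(.layerConv(3L, widths[1]), .layerBN(widths[1]),
                 .layerReLU(), .layerPool())
  inC <- widths[1]
  for (f in widths[-1]) {
    layers <- c(layers, list(
      .layerDwConv(inC), .layerBN(inC), .layerReLU(),
      .layerPwConv(inC, f), .layerBN(f), .layerReLU(), .layerPool()))
    inC <- f
  }
  c(layers, list(.layerGAP(),
                 .layerDense(inC, denseUnits), .layerReLU(),
                 .layerDense(denseUnits, 7L)))
}

.pretrainedFallback <- function(pretrained) {
  if (isTRUE(pretrained))
    warning("pretrained backbone weights are not available offline; ",
            "falling back to random initialization")
}

#' Build an MCNN2 variant
#'
#' Three-channel input per the variant table (\code{\link{mcnn2Channels}}):
#' the raw grayscale image plus two morphological residuals, feeding an
#' unchanged lightweight depthwise-separable-convolution backbone with a
#' global-average-pooling + dense head. Only the input representation differs
#' between variants; the backbone and head are identical, so all six variants
#' share one parameter count.
#'
#' @param variant "v1".."v6" (or "MCNN2v1".."MCNN2v6").
#' @param inputSide square input side (default 160).
#' @param se structuring element for the residuals (default 7x7 disk).
#' @param widths backbone stage widths.
#' @param denseUnits dense head width (default 16).
#' @param pretrained request pretrained backbone weights; unavailable offline,
#'   so this falls back to random initialization with a warning.
#' @return A \linkS4class{MorphNet}.
#' @export
buildMCNN2 <- function(variant = "v5", inputSide = 160L,
                       se = makeStructuringElement("disk", 7),
                       widths = c(16L, 32L, 64L, 128L), denseUnits = 16L,
                       pretrained = FALSE) {
  .pretrainedFallback(pretrained)
  channels <- mcnn2Channels(variant)
  v <- sub("^MCNN2", "", variant)
  .newMorphNet(paste0("MCNN2", v), channels, se, inputSide,
               .dsBackboneLayers(widths, denseUnits))
}

# Classic 19-layer-style conv stack (16 conv layers in 5 pooled stages).
.vgg19Layers <- function(denseUnits = 16L) {
  cfg <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L, 256L),
              c(512L, 512L, 512L, 512L), c(512L, 512L, 512L, 512L))
  layers <- list()
  inC <- 3L
  for (stage in cfg) {
    for (f in stage) {
      layers <- c(layers, list(.layerConv(inC, f), .layerReLU()))
      inC <- f
    }
    layers <- c(layers, list(.layerPool()))
  }
  c(layers, list(.layerGAP(),
                 .layerDense(inC, denseUnits), .layerReLU(),
                 .layerDense(denseUnits, 7L)))
}

#' Build a backbone baseline (replicated-grayscale input)
#'
#' Baselines consume the grayscale image replicated to three identical
#' channels (ablation-style replication), keeping input dimensionality and
#' parameter count identical to the MCNN2 variants. \code{"MOBILENETV2"}
#' denotes the same lightweight depthwise-separable backbone the MCNN2
#' variants use; \code{"VGG19"} is a deep high-capacity conv stack whose
#' first \code{freezeDepth} convolutional layers are frozen (0 = all layers
#' trainable).
#'
#' @param architectureId "MOBILENETV2" or "VGG19".
#' @param inputSide square input side (default 160).
#' @param freezeDepth number of leading conv layers to freeze (VGG19 only).
#' @param widths backbone widths (lightweight backbone only).
#' @param denseUnits dense head width.
#' @param pretrained see \code{\link{buildMCNN2}}.
#' @return A \linkS4class{MorphNet}.
#' @export
buildBaseline <- function(architectureId = c("MOBILENETV2", "VGG19"),
                          inputSide = 160L, freezeDepth = 0L,
                          widths = c(16L, 32L, 64L, 128L), denseUnits = 16L,
                          pretrained = FALSE) {
  architectureId <- match.arg(architectureId)
  .pretrainedFallback(pretrained)
  se <- makeStructuringElement("disk", 7)
  if (architectureId == "MOBILENETV2") {
    layers <- .dsBackboneLayers(widths, denseUnits)
  } else {
    layers <- .vgg19Layers(denseUnits)
    if (freezeDepth > 0L) {
      frozen <- 0L
      for (i in seq_along(layers)) {
        if (layers[[i]]$type == "conv") {
          layers[[i]]$trainable <- FALSE
          frozen <- frozen + 1L
          if (frozen >= freezeDepth) break
        }
      }
    }
  }
  .newMorphNet(architectureId, c("If", "If", "If"), se, inputSide, layers)
}

#' Replace morphological channels by grayscale replication (ablation)
#'
#' Implements the ablation protocol: each removed morphological channel is
#' replaced by a copy of the raw grayscale input, preserving channel count
#' and parameter count exactly. Removing every morphological channel of
#' MCNN1 yields four identical If channels.
#'
#' @param model a \linkS4class{MorphNet} (MCNN1 or an MCNN2 variant).
#' @param remove character vector of residual channels to replace (subset of
#'   the model's channels, e.g. c("Ife")), or "all".
#' @return The ablated \linkS4class{MorphNet} (same layers, new channel spec).
#' @export
#' @examples
#' m <- buildMCNN2("v5", inputSide = 48, widths = c(4, 8, 8, 8))
#' modelChannels(ablateReplicate(m, "Ife"))  # If, If, Ifo
ablateReplicate <- function(model, remove) {
  morph <- setdiff(model@channels, "If")
  if (identical(remove, "all")) remove <- unique(morph)
  if (!all(remove %in% morph))
    stop("channels not present in this model: ",
         paste(setdiff(remove, morph), collapse = ", "))
  model@channels[model@channels %in% remove] <- "If"
  model@architecture <- paste0(model@architecture, "+replicate")
  model
}

#' Count learnable parameters of a model
#'
#' Sums all learnable weight and bias entries: convolution and dense weights
#' and biases plus batch-normalization scale/offset. Batch-normalization
#' running statistics are not learnable and are excluded unless
#' \code{includeRunningStats = TRUE}. The morphological channel front-end is
#' fixed and contributes zero. With \code{trainableOnly = TRUE}, frozen
#' layers are excluded.
#'
#' @param x a \linkS4class{MorphNet}.
#' @param trainableOnly count only non-frozen layers (default FALSE).
#' @param includeRunningStats also count batch-norm running statistics.
#' @param ... unused.
#' @return integer parameter count.
#' @export
setGeneric("countParameters",
           function(x, ...) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "MorphNet",
          function(x, trainableOnly = FALSE, includeRunningStats = FALSE, ...) {
  sum(vapply(x@layers, .layerParamCount, 0L,
             trainableOnly = trainableOnly,
             includeRunningStats = includeRunningStats))
})

#' Per-layer parameter breakdown
#'
#' @param model a \linkS4class{MorphNet}.
#' @return data.frame with columns \code{layer}, \code{type},
#'   \code{parameters} (learnable, excluding batch-norm running statistics)
#'   and \code{trainable}.
#' @export
parameterBreakdown <- function(model) {
  data.frame(
    layer = seq_along(model@layers),
    type = vapply(model@layers, function(l) l$type, ""),
    parameters = vapply(model@layers, .layerParamCount, 0L),
    trainable = vapply(model@layers, function(l)
      is.null(l$trainable) || isTRUE(l$trainable), TRUE))
}

# Build the [h, w, n, C] input tensor (unit scale) for a model from
# grayscale images, applying the fixed morphological channel front-end and
# the uniform 1/255 rescale. Accepts a matrix, a list of matrices, an
# [h, w, n] gray stack, or a precomputed [h, w, n, C] channel tensor (uint8
# scale), whose channel count must match the architecture.
.modelInput <- function(model, images) {
  side <- model@inputSide
  C <- length(model@channels)
  if (is.array(images) && length(dim(images)) == 4L) {
    if (dim(images)[4] != C)
      stop(sprintf("wrong channel count for %s: expected %d, got %d",
                   model@architecture, C, dim(images)[4]))
    return(images / 255)
  }
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  n <- length(images)
  x <- array(0, c(side, side, n, C))
  for (i in seq_len(n)) {
    g <- images[[i]]
    if (methods::is(g, "GrayImage")) g <- g@pixels
    if (!all(dim(g) == c(side, side)))
      stop(sprintf("image %d is %dx%d; model expects %dx%d (preprocess first)",
                   i, nrow(g), ncol(g), side, side))
    x[, , i, ] <- morphChannels(g, model@channels, model@se)
  }
  x / 255
}

#' Predict class probabilities and labels
#'
#' Runs the fixed morphological front-end and the network in inference mode.
#' Probabilities are a valid distribution per sample (softmax); the argmax
#' label breaks ties toward the lowest class index ("angry" first).
#'
#' @param model a trained (or freshly built) \linkS4class{MorphNet}.
#' @param images grayscale matrix, list of matrices, [h,w,n] stack, or a
#'   precomputed [h,w,n,C] channel tensor on the uint8 scale.
#' @param batchSize forward batch size.
#' @return list with \code{probabilities} (n x 7 matrix, class columns) and
#'   \code{labels} (factor over the seven classes).
#' @export
predictProba <- function(model, images, batchSize = 64L) {
  x <- .modelInput(model, images)
  n <- dim(x)[3]
  cls <- expressionClasses()
  probs <- matrix(0, n, 7L, dimnames = list(NULL, cls))
  for (s in seq(1L, n, by = batchSize)) {
    e <- min(s + batchSize - 1L, n)
    xb <- x[, , s:e, , drop = FALSE]
    logits <- .nnForward(model@layers, xb, training = FALSE)$out
    probs[s:e, ] <- .softmaxProbs(logits)
  }
  idx <- max.col(probs, ties.method = "first")
  list(probabilities = probs, labels = factor(cls[idx], levels = cls))
}

#' @describeIn predictProba S4 predict method returning labels
#'   (\code{type = "class"}) or the probability matrix (\code{type = "prob"}).
#' @param object a \linkS4class{MorphNet}.
#' @param type "class" or "prob".
#' @export
setMethod("predict", "MorphNet", function(object, images, type = c("class", "prob"),
                                          batchSize = 64L, ...) {
  type <- match.arg(type)
  r <- predictProba(object, images, batchSize)
  if (type == "class") r$labels else r$probabilities
})
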