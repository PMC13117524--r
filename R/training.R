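# Training loop: seeded, augmented training stream, Adam on softmax
# cross-entropy, best-validation-epoch weight selection.

#' Training configuration
#'
#' Default training configuration: Adam with initial learning rate 1e-5,
#' sparse categorical cross-entropy, batch size 32, at most 100 epochs, and
#' selection of the epoch with the best validation accuracy. L2 weight decay
#' (1e-3) is applied to dense-layer weights. Scaled-down smoke experiments
#' use a larger learning rate and far fewer epochs.
#'
#' @param learningRate Adam learning rate (default 1e-5).
#' @param batchSize mini-batch size (default 32).
#' @param maxEpochs maximum training epochs (default 100).
#' @param seed RNG seed for shuffling and augmentation (default 42).
#' @param l2Dense L2 penalty on dense-layer weights (default 1e-3).
#' @param warmupEpochs linear learning-rate warm-up over this many initial
#'   epochs (default 0 = none). Useful for short schedules at learning
#'   rates well above the full-schedule default, where the first Adam steps
#'   can otherwise collapse the network into the uniform-prediction saddle.
#' @param augmentation an \code{\link{augmentationConfig}}, or NULL to train
#'   on plainly rescaled images. Never applied to validation/test streams.
#' @param verbose print per-epoch progress.
#' @return named list of class \code{"morphfer_train_config"}.
#' @export
trainConfig <- function(learningRate = 1e-5, batchSize = 32L, maxEpochs = 100L,
                        seed = 42L, l2Dense = 1e-3, warmupEpochs = 0L,
                        augmentation = augmentationConfig(), verbose = FALSE) {
  stopifnot(learningRate > 0, batchSize >= 1, maxEpochs >= 1, warmupEpochs >= 0)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 l2Dense = l2Dense, warmupEpochs = as.integer(warmupEpochs),
                 augmentation = augmentation,
                 verbose = isTRUE(verbose)),
            class = "morphfer_train_config")
}

#' Load catalog samples as a model-ready tensor
#'
#' Reads every image in the catalog, preprocesses it to the canonical side,
#' applies the fixed morphological channel front-end and stacks the result
#' into an [side, side, n, C] tensor on the uint8 scale (the 1/255 rescale
#' happens at model input / augmentation). Loading once and subsetting with
#' \code{\link{sampleSubset}} avoids recomputing residuals across folds and
#' seeds.
#'
#' @param catalog a \linkS4class{FaceCatalog}.
#' @param side canonical input side.
#' @param channels channel specification over \{If, Ifd, Ife, Ifo, Ifc\}.
#' @param se structuring element for the residual channels.
#' @return list of class \code{"morphfer_samples"}: \code{x} (tensor),
#'   \code{y} (integer labels 1..7), \code{subjects}, \code{labels},
#'   \code{paths}.
#' @export
loadSamples <- function(catalog, side = 160L,
                        channels = c("Ifd", "Ife", "Ifo", "Ifc"),
                        se = makeStructuringElement("disk", 7)) {
  r <- records(catalog)
  n <- nrow(r)
  cls <- expressionClasses()
  x <- array(0, c(side, side, n, length(channels)))
  for (i in seq_len(n)) {
    g <- resizeCanonical(toGrayscale(readFaceImage(r$path[i])), side)
    x[, , i, ] <- morphChannels(g@pixels, channels, se)
  }
  structure(list(x = x, y = match(r$label, cls), subjects = r$subject_id,
                 labels = r$label, paths = r$path, channels = channels,
                 side = as.integer(side)),
            class = "morphfer_samples")
}

#' Subset a loaded sample set
#'
#' @param samples a \code{"morphfer_samples"} object.
#' @param keep logical or integer index over samples.
#' @return a \code{"morphfer_samples"} object.
#' @export
sampleSubset <- function(samples, keep) {
  structure(list(x = samples$x[, , keep, , drop = FALSE],
                 y = samples$y[keep], subjects = samples$subjects[keep],
                 labels = samples$labels[keep], paths = samples$paths[keep],
                 channels = samples$channels, side = samples$side),
            class = "morphfer_samples")
}

.asSamples <- function(data, model) {
  if (inherits(data, "morphfer_samples")) {
    if (!identical(data$channels, model@channels))
      stop("sample channels (", paste(data$channels, collapse = ","),
           ") do not match the model (", paste(model@channels, collapse = ","), ")")
    if (data$side != model@inputSide)
      stop("sample side does not match the model input side")
    return(data)
  }
  if (methods::is(data, "FaceCatalog"))
    return(loadSamples(data, model@inputSide, model@channels, model@se))
  stop("expected a FaceCatalog or a morphfer_samples object")
}

# Assemble one mini-batch on the unit scale, optionally augmented.
.makeBatch <- function(samples, idx, augmentation) {
  d <- dim(samples$x)
  xb <- array(0, c(d[1], d[2], length(idx), d[4]))
  for (j in seq_along(idx)) {
    xi <- samples$x[, , idx[j], , drop = TRUE]
    if (length(dim(xi)) < 3L) dim(xi) <- c(d[1], d[2], d[4])
    xb[, , j, ] <- if (is.null(augmentation)) xi / 255
                   else augmentImage(xi, augmentation)
  }
  xb
}

.evalStream <- function(layers, samples, batchSize = 64L) {
  n <- length(samples$y)
  loss <- 0; correct <- 0L
  for (s in seq(1L, n, by = batchSize)) {
    e <- min(s + batchSize - 1L, n)
    xb <- samples$x[, , s:e, , drop = FALSE] / 255
    logits <- .nnForward(layers, xb, training = FALSE)$out
    lg <- .ceLossGrad(logits, samples$y[s:e])
    loss <- loss + lg$loss * (e - s + 1L)
    correct <- correct + sum(max.col(lg$probs, ties.method = "first") ==
                               samples$y[s:e])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Train a model
#'
#' Seeded training on the (augmented) training stream with Adam and sparse
#' categorical cross-entropy; after each epoch the validation stream is
#' scored in inference mode (never augmented) and the weights of the epoch
#' with the best validation accuracy are retained. Training and validation
#' must not share any subject identity.
#'
#' @param model a \linkS4class{MorphNet}.
#' @param train training \linkS4class{FaceCatalog} or
#'   \code{"morphfer_samples"}.
#' @param validation validation stream, same types.
#' @param cfg a \code{\link{trainConfig}}.
#' @return The trained \linkS4class{MorphNet}; its \code{trainingHistory()}
#'   carries per-epoch loss/accuracy and an attribute \code{"streams"}
#'   auditing which streams were augmented.
#' @export
trainModel <- function(model, train, validation, cfg = trainConfig()) {
  train <- .asSamples(train, model)
  validation <- .asSamples(validation, model)
  if (length(train$y) == 0L) stop("empty training stream")
  if (length(validation$y) == 0L) stop("empty validation stream")
  shared <- intersect(unique(train$subjects), unique(validation$subjects))
  if (length(shared))
    stop("identity leakage: subjects in both streams: ",
         paste(utils::head(shared, 5L), collapse = ", "))

  layers <- model@layers
  for (i in seq_along(layers))
    if (layers[[i]]$type == "dense") layers[[i]]$l2 <- cfg$l2Dense

  set.seed(cfg$seed)
  state <- .adamInit(layers)
  tStep <- 0L
  n <- length(train$y)
  best <- list(acc = -Inf, layers = layers, epoch = NA_integer_)
  hist <- vector("list", cfg$maxEpochs)

  wu <- if (is.null(cfg$warmupEpochs)) 0L else cfg$warmupEpochs
  stepsPerEpoch <- ceiling(n / cfg$batchSize)
  for (epoch in seq_len(cfg$maxEpochs)) {
    ord <- sample.int(n)
    epLoss <- 0; epCorrect <- 0L
    for (s in seq(1L, n, by = cfg$batchSize)) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
      xb <- .makeBatch(train, idx, cfg$augmentation)
      fw <- .nnForward(layers, xb, training = TRUE)
      layers <- fw$layers
      lg <- .ceLossGrad(fw$out, train$y[idx])
      grads <- .nnBackward(layers, fw$caches, lg$dlogits)
      tStep <- tStep + 1L
      lr <- cfg$learningRate *
        if (wu > 0L) min(1, tStep / (wu * stepsPerEpoch)) else 1
      upd <- .adamStep(layers, grads, state, tStep, lr)
      layers <- upd$layers; state <- upd$state
      epLoss <- epLoss + lg$loss * length(idx)
      epCorrect <- epCorrect + sum(max.col(lg$probs, ties.method = "first") ==
                                     train$y[idx])
    }
    val <- .evalStream(layers, validation)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = epLoss / n,
                                accuracy = epCorrect / n,
                                val_loss = val$loss,
                                val_accuracy = val$accuracy)
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_acc %.4f",
                      epoch, epLoss / n, epCorrect / n, val$accuracy))
    if (val$accuracy > best$acc)
      best <- list(acc = val$accuracy, layers = layers, epoch = epoch)
  }

  history <- do.call(rbind, hist[seq_len(cfg$maxEpochs)])
  attr(history, "streams") <- list(
    train_augmented = !is.null(cfg$augmentation),
    validation_augmented = FALSE)
  model@layers <- best$layers
  model@trained <- TRUE
  model@history <- history
  model@bestEpoch <- best$epoch
  model
}

#' Evaluate a model on a labeled stream
#'
#' Scores a sample stream in inference mode (no augmentation) and returns
#' the confusion matrix and the derived metrics.
#'
#' @param model a trained \linkS4class{MorphNet}.
#' @param data a \linkS4class{FaceCatalog} or \code{"morphfer_samples"}.
#' @return list with \code{confusion} (\linkS4class{ConfusionMatrix}) and
#'   \code{metrics} (see \code{\link{classMetrics}}).
#' @export
evaluateModel <- function(model, data) {
  samples <- .asSamples(data, model)
  pred <- predictProba(model, samples$x)$labels
  cm <- confusion(samples$labels, as.character(pred))
  list(confusion = cm, metrics = classMetrics(cm))
}
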