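# Confusion matrices, macro metrics, cross-validation orchestration and
# efficiency reporting.

#' Build a confusion matrix
#'
#' counts[i, j] = number of samples with true class i predicted as class j,
#' classes ordered as \code{classNames}. Rows are the true class (diagonal =
#' per-class true positives), columns the predicted class.
#'
#' @param true vector of true labels (character or factor).
#' @param predicted vector of predicted labels, same length.
#' @param classNames ordered class labels (default the seven expressions).
#' @return A \linkS4class{ConfusionMatrix}.
#' @export
#' @examples
#' confusionCounts(confusion(c("a","a","b"), c("a","b","b"), c("a","b")))
confusion <- function(true, predicted, classNames = expressionClasses()) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  tf <- factor(as.character(true), levels = classNames)
  pf <- factor(as.character(predicted), levels = classNames)
  if (anyNA(tf) || anyNA(pf)) stop("labels outside classNames")
  m <- table(tf, pf)
  methods::new("ConfusionMatrix",
               counts = matrix(as.integer(m), nrow(m), ncol(m)),
               classNames = classNames)
}

#' Accuracy and macro precision / recall / F1 from a confusion matrix
#'
#' Accuracy is the summed diagonal (true positives) over the total count.
#' Macro precision and recall are the unweighted arithmetic means of the
#' per-class values; the macro F1 is the harmonic mean of macro precision
#' and macro recall (not the mean of per-class F1 scores). A class that is
#' never predicted (zero column sum) gets per-class precision 0, and a class
#' with no true samples (zero row sum) gets per-class recall 0, each with a
#' warning.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return list with \code{accuracy}, \code{macro_precision},
#'   \code{macro_recall}, \code{macro_f1} and a \code{per_class} data.frame.
#' @export
#' @examples
#' cm <- methods::new("ConfusionMatrix",
#'                    counts = matrix(c(3L, 2L, 1L, 4L), 2, 2),
#'                    classNames = c("neg", "pos"))
#' classMetrics(cm)$accuracy  # 0.7
setGeneric("classMetrics", function(cm) standardGeneric("classMetrics"))

#' @rdname classMetrics
#' @export
setMethod("classMetrics", "ConfusionMatrix", function(cm) {
  m <- cm@counts
  total <- sum(m)
  if (total == 0L) stop("empty confusion matrix")
  tp <- diag(m)
  colS <- colSums(m)
  rowS <- rowSums(m)
  if (any(colS == 0)) warning("class never predicted; its precision set to 0")
  if (any(rowS == 0)) warning("class with no true samples; its recall set to 0")
  prec <- ifelse(colS > 0, tp / colS, 0)
  rec <- ifelse(rowS > 0, tp / rowS, 0)
  mp <- mean(prec)
  mr <- mean(rec)
  f1 <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(accuracy = sum(tp) / total,
       macro_precision = mp, macro_recall = mr, macro_f1 = f1,
       per_class = data.frame(class = cm@classNames,
                              precision = unname(prec), recall = unname(rec)))
})

.metricVec <- function(metrics) {
  unlist(metrics[c("accuracy", "macro_precision", "macro_recall", "macro_f1")])
}

#' Subject-independent k-fold cross-validation
#'
#' For each fold, the held-out fold's subjects form the test stream, a
#' subject-level validation split is carved from the remaining training
#' subjects (for best-epoch selection), a fresh model is built and trained,
#' and the test stream is scored. Per-fold metrics are aggregated as mean
#' and standard deviation.
#'
#' @param modelFactory zero-argument function returning a fresh
#'   \linkS4class{MorphNet} (fresh random initialization per fold).
#' @param catalog a \linkS4class{FaceCatalog}.
#' @param plan a \linkS4class{FoldPlan} over the catalog's subjects.
#' @param cfg a \code{\link{trainConfig}}.
#' @param valFraction fraction of training subjects carved out for
#'   validation (default 0.15).
#' @param samples optional preloaded \code{"morphfer_samples"} for the whole
#'   catalog (avoids reloading images per fold).
#' @return list with \code{perFold} (list of metric lists), \code{confusions}
#'   (list of \linkS4class{ConfusionMatrix}), and \code{summary} (data.frame
#'   of mean and sd per metric).
#' @export
runCrossval <- function(modelFactory, catalog, plan, cfg = trainConfig(),
                        valFraction = 0.15, samples = NULL) {
  k <- nFolds(plan)
  r <- records(catalog)
  perFold <- vector("list", k)
  confusions <- vector("list", k)
  for (i in seq_len(k)) {
    model <- modelFactory()
    if (is.null(samples))
      samples <- loadSamples(catalog, model@inputSide, model@channels, model@se)
    testSubs <- foldSubjects(plan, i)
    trainSubs <- setdiff(unique(r$subject_id), testSubs)
    valSubs <- .withSeed(plan@seed + i,
                         sample(trainSubs, max(1L, ceiling(valFraction * length(trainSubs)))))
    trainSubs <- setdiff(trainSubs, valSubs)
    tr <- sampleSubset(samples, samples$subjects %in% trainSubs)
    va <- sampleSubset(samples, samples$subjects %in% valSubs)
    te <- sampleSubset(samples, samples$subjects %in% testSubs)
    stopifnot(length(intersect(tr$subjects, te$subjects)) == 0L,
              length(intersect(va$subjects, te$subjects)) == 0L)
    fit <- trainModel(model, tr, va, cfg)
    ev <- evaluateModel(fit, te)
    perFold[[i]] <- ev$metrics
    confusions[[i]] <- ev$confusion
  }
  mat <- t(vapply(perFold, .metricVec, numeric(4L)))
  list(perFold = perFold, confusions = confusions,
       summary = data.frame(metric = colnames(mat),
                            mean = colMeans(mat),
                            sd = apply(mat, 2L, stats::sd),
                            row.names = NULL))
}

#' Leave-one-dataset-out (cross-dataset) evaluation
#'
#' Trains on every source corpus except the held-out one (with an internal
#' subject-independent validation split for best-epoch selection) and scores
#' the held-out source once. The training stream contains zero holdout
#' records by construction.
#'
#' @inheritParams runCrossval
#' @param holdoutSource dataset source tag to hold out.
#' @param seed seed for the validation carve.
#' @return list with \code{metrics}, \code{confusion} and the trained
#'   \code{model}.
#' @export
runCrossDataset <- function(modelFactory, catalog, holdoutSource,
                            cfg = trainConfig(), valFraction = 0.15,
                            samples = NULL, seed = 42L) {
  split <- leaveOneDatasetOut(catalog, holdoutSource)
  model <- modelFactory()
  if (is.null(samples))
    samples <- loadSamples(catalog, model@inputSide, model@channels, model@se)
  r <- records(catalog)
  isTest <- r$dataset == holdoutSource
  trainSubs <- unique(r$subject_id[!isTest])
  valSubs <- .withSeed(seed,
                       sample(trainSubs, max(1L, ceiling(valFraction * length(trainSubs)))))
  tr <- sampleSubset(samples, !isTest & !(samples$subjects %in% valSubs))
  va <- sampleSubset(samples, !isTest & samples$subjects %in% valSubs)
  te <- sampleSubset(samples, isTest)
  stopifnot(!any(te$subjects %in% tr$subjects))
  fit <- trainModel(model, tr, va, cfg)
  ev <- evaluateModel(fit, te)
  list(metrics = ev$metrics, confusion = ev$confusion, model = fit)
}

#' Inference efficiency report
#'
#' Mean single-sample prediction latency over \code{reps} repeated runs
#' (default 100) after \code{warmup} warm-up calls, plus the parameter
#' count. Accelerator memory is reported as NA when no accelerator backend
#' is present. Latency is hardware-dependent and is reported, never asserted
#' against.
#'
#' @param model a \linkS4class{MorphNet}.
#' @param probe a single grayscale matrix at the model's input side.
#' @param reps number of timed repetitions (default 100).
#' @param warmup untimed warm-up calls (default 5).
#' @return list with \code{parameter_count}, \code{mean_inference_latency_ms},
#'   \code{latencies_ms} (length \code{reps}),
#'   \code{peak_accelerator_memory_mb} (NA) and \code{n_repeats}.
#' @export
efficiencyReport <- function(model, probe, reps = 100L, warmup = 5L) {
  for (i in seq_len(warmup)) predictProba(model, probe)
  lat <- vapply(seq_len(reps), function(i) {
    t0 <- Sys.time()
    predictProba(model, probe)
    as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  }, 0)
  list(parameter_count = countParameters(model),
       mean_inference_latency_ms = mean(lat),
       latencies_ms = lat,
       peak_accelerator_memory_mb = NA_real_,
       n_repeats = as.integer(reps))
}
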