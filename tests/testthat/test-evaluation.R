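test_that("confusion matrices count true-by-predicted pairs", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(unname(confusionCounts(cm)), matrix(c(1L, 0L, 1L, 1L), 2, 2))

  set.seed(9)
  cls <- expressionClasses()
  true <- sample(cls, 60, replace = TRUE)
  pred <- sample(cls, 60, replace = TRUE)
  cm7 <- confusion(true, pred)
  expect_equal(unname(rowSums(confusionCounts(cm7))),
               as.vector(table(factor(true, cls))))
  expect_equal(sum(confusionCounts(cm7)), 60)

  perfect <- confusion(cls, cls)
  expect_equal(unname(confusionCounts(perfect)), diag(1L, 7))
  expect_error(confusion(c("a"), c("zz"), c("a", "b")), "classNames")
})

test_that("metrics reproduce hand computations and edge cases", {
  idm <- methods::new("ConfusionMatrix", counts = diag(5L, 4),
                      classNames = letters[1:4])
  m <- classMetrics(idm)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_precision, 1)
  expect_equal(m$macro_recall, 1)
  expect_equal(m$macro_f1, 1)

  # 2-class worked example: [[3,1],[2,4]]
  cm <- methods::new("ConfusionMatrix",
                     counts = matrix(c(3L, 2L, 1L, 4L), 2, 2),
                     classNames = c("neg", "pos"))
  m <- classMetrics(cm)
  expect_equal(m$accuracy, 0.7, tolerance = 1e-9)
  expect_equal(m$macro_precision, 0.7, tolerance = 1e-9)
  expect_equal(m$macro_recall, 0.708333333, tolerance = 1e-6)
  expect_equal(m$macro_f1, 0.704142012, tolerance = 1e-6)

  allWrong <- methods::new("ConfusionMatrix",
                           counts = matrix(c(0L, 3L, 2L, 0L), 2, 2),
                           classNames = c("neg", "pos"))
  expect_equal(classMetrics(allWrong)$accuracy, 0)

  # zero-division convention: a never-predicted class scores precision 0
  cmz <- methods::new("ConfusionMatrix",
                      counts = matrix(c(2L, 1L, 0L, 0L), 2, 2),
                      classNames = c("neg", "pos"))
  expect_warning(mz <- classMetrics(cmz), "never predicted")
  expect_equal(mz$per_class$precision[2], 0)
})

test_that("the macro F1 is the harmonic mean of macro precision and recall", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:7, 1)
    counts <- matrix(rpois(n * n, 4), n, n)
    diag(counts) <- diag(counts) + 1L  # keep rows/cols occupied
    cm <- methods::new("ConfusionMatrix", counts = counts,
                       classNames = paste0("c", seq_len(n)))
    m <- suppressWarnings(classMetrics(cm))
    expect_equal(m$macro_f1,
                 2 * m$macro_precision * m$macro_recall /
                   (m$macro_precision + m$macro_recall))
    expect_equal(m$accuracy, sum(diag(counts)) / sum(counts))
    expect_true(m$macro_f1 <= max(m$macro_precision, m$macro_recall) + 1e-12)
    expect_true(m$macro_f1 >= min(m$macro_precision, m$macro_recall) - 1e-12)
  }
})

test_that("metrics are invariant under simultaneous class relabeling", {
  set.seed(22)
  counts <- matrix(rpois(16, 5) + 1L, 4, 4)
  cm <- methods::new("ConfusionMatrix", counts = counts,
                     classNames = paste0("c", 1:4))
  perm <- sample(4)
  cmP <- methods::new("ConfusionMatrix", counts = counts[perm, perm],
                      classNames = paste0("c", 1:4)[perm])
  a <- classMetrics(cm); b <- classMetrics(cmP)
  for (f in c("accuracy", "macro_precision", "macro_recall", "macro_f1"))
    expect_equal(a[[f]], b[[f]])
})

test_that("cross-validation aggregates fold metrics and audits identity leakage", {
  catalog <- tinyCorpus(nSubjects = 8, perClass = 1, nSources = 2, side = 48)
  plan <- subjectIndependentFolds(catalog, k = 2, seed = 42)
  factory <- function() buildMCNN2("v5", inputSide = 32, widths = c(4, 4, 4, 4),
                                  denseUnits = 8)
  samples <- loadSamples(catalog, 32, mcnn2Channels("v5"))
  res <- suppressWarnings(
    runCrossval(factory, catalog, plan, tinyTrainConfig(epochs = 2),
                valFraction = 0.25, samples = samples))
  expect_length(res$perFold, 2)
  expect_length(res$confusions, 2)
  accs <- vapply(res$perFold, function(m) m$accuracy, 0)
  expect_equal(res$summary$mean[res$summary$metric == "accuracy"], mean(accs))
  expect_equal(res$summary$sd[res$summary$metric == "accuracy"], stats::sd(accs))
  expect_equal(sum(sapply(res$confusions, function(cm) sum(confusionCounts(cm)))),
               nSamples(catalog))
})

test_that("cross-dataset evaluation scores only the held-out source", {
  catalog <- tinyCorpus(nSubjects = 9, perClass = 1, nSources = 3, side = 48)
  factory <- function() buildMCNN2("v5", inputSide = 32, widths = c(4, 4, 4, 4),
                                  denseUnits = 8)
  samples <- loadSamples(catalog, 32, mcnn2Channels("v5"))
  res <- suppressWarnings(
    runCrossDataset(factory, catalog, "SYNTH_C",
                    tinyTrainConfig(epochs = 1), valFraction = 0.25,
                    samples = samples))
  nHold <- sum(records(catalog)$dataset == "SYNTH_C")
  expect_equal(sum(confusionCounts(res$confusion)), nHold)
  expect_error(runCrossDataset(factory, catalog, "NOPE",
                               tinyTrainConfig(epochs = 1)), "available")
})

test_that("the efficiency report times the requested number of repeats", {
  m <- buildMCNN2("v5", inputSide = 32, widths = c(4, 4, 4, 4), denseUnits = 4)
  probe <- randomUint8(32, 32)
  rep <- efficiencyReport(m, probe, reps = 100, warmup = 2)
  expect_length(rep$latencies_ms, 100)
  expect_true(all(is.finite(rep$latencies_ms)) && all(rep$latencies_ms >= 0))
  expect_equal(rep$parameter_count, countParameters(m))
  expect_true(is.na(rep$peak_accelerator_memory_mb))
})
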