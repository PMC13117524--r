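# Small synthetic corpora shared across test files, generated once per run.

.corpusCache <- new.env(parent = emptyenv())

tinyCorpus <- function(nSubjects = 10, perClass = 1, nSources = 2,
                       seed = 7, side = 64) {
  key <- paste(nSubjects, perClass, nSources, seed, side, sep = "_")
  if (is.null(.corpusCache[[key]])) {
    dir <- file.path(tempdir(), paste0("corpus_", key))
    .corpusCache[[key]] <- generateCorpus(nSubjects, perClass, nSources,
                                          seed = seed, dir = dir, side = side)
  }
  .corpusCache[[key]]
}

tinyTrainConfig <- function(epochs = 2, seed = 1, lr = 1e-3) {
  trainConfig(learningRate = lr, batchSize = 16, maxEpochs = epochs, seed = seed)
}
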