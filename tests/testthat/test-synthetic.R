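test_that("renders are deterministic given the RNG state", {
  set.seed(31); sp <- subjectParams("s01")
  ep <- expressionParams("happy", jitterSd = 0)
  a <- renderFace(sp, ep, noiseSd = 0)
  b <- renderFace(sp, ep, noiseSd = 0)
  expect_identical(pixels(a), pixels(b))
  set.seed(77); n1 <- renderFace(sp, ep, noiseSd = 3)
  set.seed(77); n2 <- renderFace(sp, ep, noiseSd = 3)
  expect_identical(pixels(n1), pixels(n2))
})

test_that("expression templates order deformations as the classes demand", {
  tpl <- expressionTemplates()
  g <- function(l, f) tpl[tpl$label == l, f]
  expect_gt(g("surprise", "mouthOpen"), g("neutral", "mouthOpen"))
  expect_gt(g("surprise", "eyeAperture"), g("angry", "eyeAperture"))
  expect_gt(g("happy", "mouthCurv"), 0)
  expect_lt(g("sad", "mouthCurv"), 0)
  expect_equal(nrow(tpl), 7)
  expect_setequal(tpl$label, expressionClasses())
})

test_that("erosion residuals localize on feature edges, not flat background", {
  set.seed(32); sp <- subjectParams("s01")
  img <- pixels(renderFace(sp, expressionParams("neutral", 0), noiseSd = 0))
  r <- morphResiduals(img, makeStructuringElement("disk", 7))
  expect_equal(r$ife[1:10, 1:10], matrix(0, 10, 10))  # flat corner background
  mouthRows <- round(0.66 * 160):round(0.74 * 160)
  expect_gt(sum(r$ife[mouthRows, ] > 0), 0)           # mass at the mouth edges
  browRows <- round(0.30 * 160):round(0.40 * 160)
  expect_gt(sum(r$ife[browRows, ] > 0), 0)            # mass at eyes/brows
})

test_that("the corpus catalog has the promised size and structure", {
  cat0 <- tinyCorpus(nSubjects = 10, perClass = 2, nSources = 2, seed = 7, side = 48)
  expect_equal(nSamples(cat0), 10 * 7 * 2)
  r <- records(cat0)
  expect_true(all(table(r$subject_id) == 14))
  bySub <- tapply(r$dataset, r$subject_id, function(d) length(unique(d)))
  expect_true(all(bySub == 1))                        # one source per subject
  expect_true(all(file.exists(r$path)))
})

test_that("corpus generation is byte-identical under a fixed seed", {
  d <- file.path(tempdir(), "regen")
  c1 <- generateCorpus(4, 1, 2, seed = 5, dir = d, side = 48)
  bytes1 <- readBin(file.path(d, "catalog.csv"), "raw", 1e6)
  img1 <- readBin(records(c1)$path[1], "raw", 1e6)
  c2 <- generateCorpus(4, 1, 2, seed = 5, dir = d, side = 48)
  bytes2 <- readBin(file.path(d, "catalog.csv"), "raw", 1e6)
  img2 <- readBin(records(c2)$path[1], "raw", 1e6)
  expect_identical(bytes1, bytes2)
  expect_identical(img1, img2)
  expect_identical(records(c1), records(c2))
})

test_that("noiseless renders are perfectly separated by their class templates", {
  set.seed(33)
  tpl <- expressionClasses()
  ok <- 0L; tot <- 0L
  for (s in 1:6) {
    sp <- subjectParams(sprintf("t%02d", s))
    templates <- sapply(tpl, function(l)
      as.vector(pixels(renderFace(sp, expressionParams(l, 0), noiseSd = 0))))
    for (l in tpl) {
      x <- as.vector(pixels(renderFace(sp, expressionParams(l, 1), noiseSd = 0)))
      pred <- tpl[which.min(colSums((templates - x)^2))]
      ok <- ok + (pred == l); tot <- tot + 1L
    }
  }
  expect_equal(ok, tot)  # 100%: the corpus carries learnable class signal
})

test_that("identity leakage inflates a naive classifier's accuracy", {
  # 1-NN on raw pixels: in a subject-dependent split every test image has a
  # same-subject, same-class sibling in training, so the classifier matches
  # the identity rather than generalizing the expression and scores
  # perfectly; a subject-independent split removes that shortcut and the
  # accuracy drops. This is the inflation the protocol guards against.
  catalog <- tinyCorpus(nSubjects = 10, perClass = 2, nSources = 2, seed = 7, side = 48)
  samples <- loadSamples(catalog, side = 32, channels = "If")
  X <- t(apply(samples$x[, , , 1], 3, as.vector))
  y <- samples$y; subj <- samples$subjects
  oneNN <- function(trainIdx, testIdx) {
    pred <- vapply(testIdx, function(i) {
      d2 <- rowSums((X[trainIdx, , drop = FALSE] -
                       matrix(X[i, ], length(trainIdx), ncol(X), byrow = TRUE))^2)
      y[trainIdx[which.min(d2)]]
    }, 0L)
    mean(pred == y[testIdx])
  }
  # subject-dependent: first image of each subject-class pair trains, the
  # sibling is tested (all subjects seen in training)
  secondOfPair <- grepl("_2[.]png$", records(catalog)$path)
  accDep <- oneNN(which(!secondOfPair), which(secondOfPair))
  # subject-independent: half of the subjects held out entirely
  set.seed(44)
  half <- sample(unique(subj), length(unique(subj)) %/% 2)
  ti <- which(subj %in% half)
  accInd <- oneNN(setdiff(seq_along(y), ti), ti)
  expect_gt(accDep, accInd)
})

test_that("holding out a source is harder than a pooled subject split", {
  catalog <- tinyCorpus(nSubjects = 12, perClass = 1, nSources = 3, seed = 9, side = 48)
  samples <- loadSamples(catalog, side = 32, channels = "If")
  X <- t(apply(samples$x[, , , 1], 3, as.vector))
  y <- samples$y; subj <- samples$subjects; src <- records(catalog)$dataset
  centroidAcc <- function(trainIdx, testIdx) {
    cent <- sapply(1:7, function(k) {
      idx <- trainIdx[y[trainIdx] == k]
      if (!length(idx)) return(rep(Inf, ncol(X)))
      colMeans(X[idx, , drop = FALSE])
    })
    pred <- apply(X[testIdx, , drop = FALSE], 1, function(v)
      which.min(colSums((cent - v)^2)))
    mean(pred == y[testIdx])
  }
  losoAcc <- mean(sapply(unique(src), function(s) {
    centroidAcc(which(src != s), which(src == s))
  }))
  set.seed(55)
  pooledAcc <- mean(sapply(1:3, function(r) {
    half <- sample(unique(subj), length(unique(subj)) %/% 3)
    ti <- which(subj %in% half)
    centroidAcc(setdiff(seq_along(y), ti), ti)
  }))
  expect_gte(pooledAcc, losoAcc)  # source shift makes transfer harder on average
})
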