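fakeCatalog <- function(nSubjects, perSubject = 2, sources = NULL) {
  cls <- expressionClasses()
  subs <- sprintf("p%02d", seq_len(nSubjects))
  if (is.null(sources)) sources <- rep("A", nSubjects)
  rows <- do.call(rbind, lapply(seq_len(nSubjects), function(i) {
    data.frame(path = sprintf("%s_%d.png", subs[i], seq_len(perSubject)),
               subject_id = subs[i], dataset = sources[i],
               label = cls[(i + seq_len(perSubject)) %% 7 + 1])
  }))
  FaceCatalog(rows)
}

test_that("catalog validity enforces the bookkeeping invariants", {
  expect_error(FaceCatalog(data.frame(path = c("a", "a"), subject_id = "s",
                                      dataset = "A", label = "happy")),
               "duplicate")
  expect_error(FaceCatalog(data.frame(path = c("a", "b"), subject_id = "s",
                                      dataset = c("A", "B"), label = "happy")),
               "single dataset")
  expect_error(FaceCatalog(data.frame(path = "a", subject_id = "s",
                                      dataset = "A", label = "smiling")),
               "label")
  cat10 <- fakeCatalog(10)
  expect_equal(nSamples(cat10), 20)
  expect_equal(length(subjectIds(cat10)), 10)
})

test_that("subject folds are disjoint, exhaustive and balanced", {
  cat10 <- fakeCatalog(10)
  plan <- subjectIndependentFolds(cat10, k = 10, seed = 42)
  expect_equal(nFolds(plan), 10)
  expect_equal(vapply(seq_len(10), function(i) length(foldSubjects(plan, i)), 1L),
               rep(1L, 10))

  cat23 <- fakeCatalog(23)
  plan23 <- subjectIndependentFolds(cat23, k = 10, seed = 42)
  sizes <- sort(vapply(seq_len(10), function(i) length(foldSubjects(plan23, i)), 1L))
  expect_equal(sizes, sort(c(3L, 3L, 3L, rep(2L, 7))))  # round-robin deal
  all_s <- unlist(lapply(seq_len(10), foldSubjects, x = plan23))
  expect_equal(sort(all_s), subjectIds(cat23))          # exhaustive, disjoint
  expect_equal(anyDuplicated(all_s), 0L)

  expect_error(subjectIndependentFolds(fakeCatalog(5), k = 10), "subjects")
})

test_that("fold plans are deterministic in the seed and serializable", {
  cat23 <- fakeCatalog(23)
  p1 <- subjectIndependentFolds(cat23, 10, seed = 42)
  p2 <- subjectIndependentFolds(cat23, 10, seed = 42)
  expect_identical(p1@folds, p2@folds)
  p3 <- subjectIndependentFolds(cat23, 10, seed = 43)
  expect_false(identical(p1@folds, p3@folds))

  f <- tempfile(fileext = ".json")
  writeFoldPlan(p1, f)
  expect_identical(readFoldPlan(f)@folds, p1@folds)
  # seeded shuffling must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(subjectIndependentFolds(cat23, 10, 42)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("fold splits partition the catalog with no shared identities", {
  cat12 <- fakeCatalog(12)
  plan <- subjectIndependentFolds(cat12, k = 4, seed = 1)
  for (i in 1:4) {
    sp <- foldSplit(cat12, plan, i)
    trS <- unique(records(sp$train)$subject_id)
    vaS <- unique(records(sp$validation)$subject_id)
    expect_length(intersect(trS, vaS), 0)
    expect_equal(nSamples(sp$train) + nSamples(sp$validation), nSamples(cat12))
  }
  expect_error(foldSplit(cat12, plan, 9), "fold index")
  sp1 <- foldSplit(cat12, plan, 1)
  expect_setequal(unique(records(sp1$validation)$subject_id), foldSubjects(plan, 1))
})

test_that("leave-one-dataset-out isolates the holdout source", {
  srcs <- rep(c("CKP", "JAFFE", "KDEF", "TFEID", "IFE"), each = 3)
  cat15 <- fakeCatalog(15, sources = srcs)
  sp <- leaveOneDatasetOut(cat15, "TFEID")
  expect_setequal(unique(records(sp$train)$dataset), c("CKP", "JAFFE", "KDEF", "IFE"))
  expect_equal(unique(records(sp$test)$dataset), "TFEID")
  expect_error(leaveOneDatasetOut(cat15, "XX"), "available: CKP, IFE, JAFFE, KDEF, TFEID")

  catAB <- fakeCatalog(6, sources = rep(c("A", "B"), each = 3))
  expect_equal(unique(records(leaveOneDatasetOut(catAB, "B")$train)$dataset), "A")
  catAll <- fakeCatalog(4, sources = rep("ONLY", 4))
  expect_error(leaveOneDatasetOut(catAll, "ONLY"), "empty")
})

test_that("validation carve keeps subjects disjoint", {
  cat12 <- fakeCatalog(12)
  cv <- validationCarve(cat12, fraction = 0.25, seed = 3)
  expect_length(intersect(unique(records(cv$train)$subject_id),
                          unique(records(cv$validation)$subject_id)), 0)
  expect_equal(nSamples(cv$train) + nSamples(cv$validation), nSamples(cat12))
})

test_that("identity augmentation reduces to plain rescale", {
  cfg <- augmentationConfig(horizontalFlip = FALSE, zoomMax = 0,
                            shiftMax = 0, brightnessRange = c(1, 1))
  img <- array(randomUint8(8, 8), c(8, 8, 1))
  set.seed(1)
  expect_equal(augmentImage(img, cfg), img / 255)
})

test_that("horizontal flip mirrors a lateral gradient", {
  cfg <- augmentationConfig(horizontalFlip = TRUE, zoomMax = 0,
                            shiftMax = 0, brightnessRange = c(1, 1))
  grad <- array(rep(seq(0, 255, length.out = 10), each = 10), c(10, 10, 1))
  # find a draw that flips
  set.seed(2)
  repeat {
    st <- .Random.seed
    out <- augmentImage(grad, cfg)
    if (!isTRUE(all.equal(out, grad / 255))) break
  }
  expect_equal(out[, , 1], (grad / 255)[, 10:1, 1])
})

test_that("brightness multiplies and clips on the unit scale", {
  cfg <- augmentationConfig(horizontalFlip = FALSE, zoomMax = 0,
                            shiftMax = 0, brightnessRange = c(1.2, 1.2))
  img <- array(200, c(5, 5, 2))
  out <- augmentImage(img, cfg)
  expect_equal(out, array(200 / 255 * 1.2, c(5, 5, 2)), tolerance = 1e-12)
  bright <- array(240, c(5, 5, 1))
  expect_equal(augmentImage(bright, cfg), array(1, c(5, 5, 1)))  # clipped
})

test_that("the augmentation policy contains no rotation transform", {
  cfg <- augmentationConfig()
  expect_named(cfg, c("rescale", "horizontalFlip", "zoomMax", "shiftMax",
                      "brightnessRange"))
  expect_false(any(grepl("rot", names(cfg), ignore.case = TRUE)))
})

test_that("augmentation is deterministic given the RNG state", {
  cfg <- augmentationConfig()
  img <- array(randomUint8(12, 12), c(12, 12, 3))
  set.seed(7); a <- augmentImage(img, cfg)
  set.seed(7); b <- augmentImage(img, cfg)
  expect_identical(a, b)
})
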