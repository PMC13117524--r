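# Catalog bookkeeping, subject-independent partitioning and the
# training-only augmentation policy.

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write a sample catalog CSV
#'
#' The catalog format is a UTF-8 CSV with header
#' \code{path,subject_id,dataset,label}, one sample per row.
#'
#' @param path CSV file path.
#' @return \code{readCatalog}: a \linkS4class{FaceCatalog}.
#' @export
readCatalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  FaceCatalog(df)
}

#' @rdname readCatalog
#' @param catalog a \linkS4class{FaceCatalog}.
#' @return \code{writeCatalog}: \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  utils::write.csv(records(catalog), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subject-independent k-fold partition
#'
#' Shuffles the (sorted) distinct subject identifiers with a seeded generator
#' and deals them round-robin into k folds, so fold sizes differ by at most
#' one. The partition is by identity, not by sample, which is what prevents
#' identity leakage between training and evaluation streams. Deterministic
#' for fixed (catalog, k, seed); the caller's RNG state is left untouched.
#'
#' @param catalog a \linkS4class{FaceCatalog}.
#' @param k number of folds (default 10).
#' @param seed integer shuffle seed (default 42).
#' @return A \linkS4class{FoldPlan}.
#' @export
#' @examples
#' # 23 subjects into 10 folds -> sizes 3,3,3,2,2,2,2,2,2,2
subjectIndependentFolds <- function(catalog, k = 10L, seed = 42L) {
  k <- as.integer(k)
  subs <- subjectIds(catalog)
  if (k < 2L) stop("k must be >= 2")
  if (length(subs) < k)
    stop(sprintf("need at least k=%d distinct subjects, found %d", k, length(subs)))
  perm <- .withSeed(seed, sample(subs))
  folds <- split(perm, rep_len(seq_len(k), length(perm)))
  names(folds) <- NULL
  methods::new("FoldPlan", folds = folds, seed = as.integer(seed))
}

.catalogSubset <- function(catalog, keep) FaceCatalog(records(catalog)[keep, , drop = FALSE])

#' Split a catalog by a fold plan
#'
#' Records of subjects in the held-out fold form the evaluation stream; all
#' other records form the training stream. No subject appears on both sides
#' and the two streams partition the catalog.
#'
#' @param catalog a \linkS4class{FaceCatalog}.
#' @param plan a \linkS4class{FoldPlan}.
#' @param heldOutFold fold index in 1..k.
#' @return list with \code{train} and \code{validation} FaceCatalogs.
#' @export
foldSplit <- function(catalog, plan, heldOutFold) {
  held <- foldSubjects(plan, heldOutFold)
  r <- records(catalog)
  inHeld <- r$subject_id %in% held
  if (!any(inHeld)) warning("held-out fold contributes no records")
  list(train = .catalogSubset(catalog, !inHeld),
       validation = .catalogSubset(catalog, inHeld))
}

#' Leave-one-dataset-out split
#'
#' All records of the held-out source corpus form the test stream; records of
#' every other source form the training stream. This is the cross-dataset
#' protocol probing robustness to domain shift.
#'
#' @param catalog a \linkS4class{FaceCatalog}.
#' @param holdoutSource dataset source tag to hold out (e.g. "TFEID").
#' @return list with \code{train} and \code{test} FaceCatalogs.
#' @export
leaveOneDatasetOut <- function(catalog, holdoutSource) {
  src <- datasetSources(catalog)
  if (!holdoutSource %in% src)
    stop("unknown source '", holdoutSource, "'; available: ",
         paste(src, collapse = ", "))
  r <- records(catalog)
  test <- r$dataset == holdoutSource
  if (all(test))
    stop("holdout source contains every record; training stream would be empty")
  list(train = .catalogSubset(catalog, !test),
       test = .catalogSubset(catalog, test))
}

#' Carve a subject-independent validation split from a training catalog
#'
#' Used where the protocol needs both a validation stream (epoch selection)
#' and a test stream (the held-out fold or source): a fraction of the
#' training subjects is moved to validation so no identity is shared.
#'
#' @param catalog training \linkS4class{FaceCatalog}.
#' @param fraction fraction of training subjects used for validation.
#' @param seed shuffle seed.
#' @return list with \code{train} and \code{validation} FaceCatalogs.
#' @export
validationCarve <- function(catalog, fraction = 0.15, seed = 42L) {
  subs <- subjectIds(catalog)
  nVal <- max(1L, ceiling(fraction * length(subs)))
  if (nVal >= length(subs)) stop("validation fraction leaves no training subjects")
  valSubs <- .withSeed(seed, sample(subs, nVal))
  r <- records(catalog)
  inVal <- r$subject_id %in% valSubs
  list(train = .catalogSubset(catalog, !inVal),
       validation = .catalogSubset(catalog, inVal))
}

#' Serialize / read a fold plan as JSON
#'
#' Format: \code{{"seed": 42, "folds": [["s01", ...], ...]}}.
#'
#' @param plan a \linkS4class{FoldPlan}.
#' @param path JSON file path.
#' @export
writeFoldPlan <- function(plan, path) {
  jsonlite::write_json(list(seed = plan@seed, folds = plan@folds),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFoldPlan
#' @export
readFoldPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(x$folds, as.character)
  methods::new("FoldPlan", folds = folds, seed = as.integer(x$seed))
}

#' Training-stream augmentation policy
#'
#' The training-stream augmentation policy: rescale to [0, 1], horizontal flip with
#' probability 1/2, uniform zoom up to +/- \code{zoomMax}, width/height shift
#' up to +/- \code{shiftMax} of the side, and a multiplicative brightness
#' factor drawn from \code{brightnessRange}, clipped to [0, 1]. Rotation is
#' deliberately absent from the policy. Augmentation is applied only to
#' training streams, never to validation or test streams.
#'
#' @param rescale multiplicative rescale applied first (default 1/255).
#' @param horizontalFlip enable random horizontal flips (default TRUE).
#' @param zoomMax maximum zoom fraction (default 0.10).
#' @param shiftMax maximum shift fraction of the side (default 0.05).
#' @param brightnessRange two-element multiplicative range (default 0.8-1.2).
#' @return A named list of class \code{"morphfer_augmentation"}.
#' @export
augmentationConfig <- function(rescale = 1 / 255, horizontalFlip = TRUE,
                               zoomMax = 0.10, shiftMax = 0.05,
                               brightnessRange = c(0.8, 1.2)) {
  stopifnot(zoomMax >= 0, zoomMax < 1, shiftMax >= 0, shiftMax < 1,
            length(brightnessRange) == 2L, all(brightnessRange > 0),
            brightnessRange[1] <= brightnessRange[2])
  structure(list(rescale = rescale, horizontalFlip = isTRUE(horizontalFlip),
                 zoomMax = zoomMax, shiftMax = shiftMax,
                 brightnessRange = brightnessRange),
            class = "morphfer_augmentation")
}

# Bilinear sample of matrix m at fractional (row, col) coordinates with edge
# clamping. rr, cc are equal-length vectors.
.bilinear <- function(m, rr, cc) {
  h <- nrow(m); w <- ncol(m)
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  r0 <- pmin(floor(rr), h - 1L); c0 <- pmin(floor(cc), w - 1L)
  fr <- rr - r0; fc <- cc - c0
  i00 <- (c0 - 1) * h + r0
  v <- m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + h] * (1 - fr) * fc + m[i00 + h + 1] * fr * fc
  v
}

#' Apply the augmentation policy to one multi-channel image
#'
#' Draws the flip/zoom/shift/brightness parameters from the current RNG
#' stream (deterministic given the RNG state) and applies, in order: rescale,
#' optional horizontal flip, a shared zoom + shift resampling (bilinear,
#' edge-replicated) across all channels, then the brightness factor with
#' clipping to [0, 1].
#'
#' @param img h x w x C numeric array (or matrix) on the uint8 scale.
#' @param cfg an \code{\link{augmentationConfig}}.
#' @return array of the same dimensions, values in [0, 1].
#' @export
augmentImage <- function(img, cfg = augmentationConfig()) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  h <- d[1]; w <- d[2]; C <- d[3]
  out <- img * cfg$rescale
  if (cfg$horizontalFlip && stats::runif(1) < 0.5)
    out <- out[, w:1, , drop = FALSE]
  zf <- if (cfg$zoomMax > 0) stats::runif(1, 1 - cfg$zoomMax, 1 + cfg$zoomMax) else 1
  sr <- if (cfg$shiftMax > 0) stats::runif(1, -cfg$shiftMax, cfg$shiftMax) * h else 0
  sc <- if (cfg$shiftMax > 0) stats::runif(1, -cfg$shiftMax, cfg$shiftMax) * w else 0
  if (zf != 1 || sr != 0 || sc != 0) {
    cr <- (h + 1) / 2; ccen <- (w + 1) / 2
    rr <- cr + (seq_len(h) - cr) / zf - sr
    cc <- ccen + (seq_len(w) - ccen) / zf - sc
    grid_r <- rep(rr, times = w)
    grid_c <- rep(cc, each = h)
    for (ch in seq_len(C))
      out[, , ch] <- matrix(.bilinear(out[, , ch], grid_r, grid_c), h, w)
  }
  br <- cfg$brightnessRange
  bf <- if (br[1] == br[2]) br[1] else stats::runif(1, br[1], br[2])
  out <- pmin(pmax(out * bf, 0), 1)
  out
}
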