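# Deterministic parametric generator of multi-subject, multi-source,
# seven-class face-like images. Expressions are encoded purely as geometric
# deformations (eyebrow angle/raise, mouth curvature/openness, eye aperture)
# on top of subject-level base geometry (face ellipse, inter-eye distance,
# skin tone) with source-level intensity/illumination offsets -- mirroring
# the structure a morphology-based pipeline is supposed to pick up, without
# any claim to photorealism.

#' Fixed expression parameter templates
#'
#' Each of the seven classes maps to a distinct deformation template:
#' \code{browAngle} (degrees, mirrored between the two brows; negative pulls
#' the inner ends down), \code{browRaise} (fraction of the side the brows
#' move up), \code{mouthCurv} (signed; positive curves the mouth corners up),
#' \code{mouthOpen} (fraction controlling mouth thickness/openness) and
#' \code{eyeAperture} (relative eye height). Per-sample Gaussian jitter is
#' added on top by \code{\link{expressionParams}}.
#'
#' @return data.frame with one row per expression class.
#' @export
expressionTemplates <- function() {
  data.frame(
    label       = expressionClasses(),
    browAngle   = c(-28,  -12,   10,    4,    0,  -14,   16),
    browRaise   = c(-0.030, -0.012, 0.022, 0.000, 0.000, 0.012, 0.040),
    mouthCurv   = c(-0.30, -0.55, -0.25, 0.90, 0.00, -0.90, 0.00),
    mouthOpen   = c(0.10,  0.32, 0.45, 0.18, 0.05, 0.04, 0.80),
    eyeAperture = c(0.55,  0.45, 1.25, 0.90, 1.00, 0.70, 1.40))
}

#' Draw subject-level base geometry
#'
#' Samples a subject's face-ellipse axes, inter-eye distance, feature
#' anchor rows and base skin intensity from the current RNG stream. All
#' geometry is stored as fractions of the canvas side, so the same subject
#' can be rendered at any canvas size.
#'
#' @param subjectId subject identifier string.
#' @param skinOffset additive source-level skin intensity offset.
#' @return named list of subject parameters.
#' @export
subjectParams <- function(subjectId, skinOffset = 0) {
  # Gross placement is narrow (face-crop preprocessing centers real faces);
  # identity lives mainly in inter-eye distance, face axes and skin tone.
  list(subjectId = subjectId,
       cx = 0.5 + stats::runif(1, -0.01, 0.01),
       cy = 0.52 + stats::runif(1, -0.008, 0.008),
       faceA = stats::runif(1, 0.32, 0.37),   # x semi-axis
       faceB = stats::runif(1, 0.41, 0.45),   # y semi-axis
       eyeDist = stats::runif(1, 0.28, 0.36),
       eyeY = stats::runif(1, 0.41, 0.43),
       mouthY = stats::runif(1, 0.68, 0.71),
       skin = min(220, max(90, stats::runif(1, 120, 205) + skinOffset)),
       featureInt = stats::runif(1, 35, 55))
}

#' Draw per-sample expression parameters
#'
#' Takes the class template and adds Gaussian jitter (disabled with
#' \code{jitterSd = 0} for noiseless template renders).
#'
#' @param label one of the seven expression classes.
#' @param jitterSd jitter scale multiplier (default 1).
#' @return named list of expression parameters.
#' @export
expressionParams <- function(label, jitterSd = 1) {
  tpl <- expressionTemplates()
  row <- tpl[tpl$label == label, ]
  if (nrow(row) != 1L) stop("unknown expression label: ", label)
  list(label = label,
       browAngle = row$browAngle + stats::rnorm(1, 0, 3 * jitterSd),
       browRaise = row$browRaise + stats::rnorm(1, 0, 0.004 * jitterSd),
       mouthCurv = row$mouthCurv + stats::rnorm(1, 0, 0.06 * jitterSd),
       mouthOpen = max(0, row$mouthOpen + stats::rnorm(1, 0, 0.04 * jitterSd)),
       eyeAperture = max(0.2, row$eyeAperture + stats::rnorm(1, 0, 0.06 * jitterSd)))
}

#' Render one synthetic face image
#'
#' Draws a face ellipse with two aperture-scaled eyes, two angle-rotated
#' eyebrow bars, a nose bar and a curvature/openness-controlled mouth band
#' on a dark background, then applies a linear illumination gradient and
#' additive Gaussian noise, clipping and rounding to the uint8 grid. The
#' render is deterministic given the RNG state (only the noise draws
#' consume randomness). Feature geometry that would leave the canvas is
#' clipped with a warning.
#'
#' @param sp subject parameters (\code{\link{subjectParams}}).
#' @param ep expression parameters (\code{\link{expressionParams}}).
#' @param side canvas side in pixels (default 160, the canonical input side).
#' @param noiseSd additive Gaussian noise standard deviation (gray levels).
#' @param illumination length-2 numeric c(gx, gy): linear gradient amplitude
#'   in gray levels across the width and height.
#' @return A \linkS4class{GrayImage} (uint8).
#' @export
renderFace <- function(sp, ep, side = 160L, noiseSd = 4,
                       illumination = c(0, 0)) {
  s <- as.integer(side)
  X <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  Y <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  cx <- sp$cx * s; cy <- sp$cy * s
  img <- matrix(30, s, s)                        # background

  face <- ((X - cx) / (sp$faceA * s))^2 + ((Y - cy) / (sp$faceB * s))^2 <= 1
  img[face] <- sp$skin

  mo <- ep$mouthOpen
  if (mo > 0.9) { warning("mouth openness clipped to canvas-safe range"); mo <- 0.9 }
  ap <- ep$eyeAperture
  if (ap > 1.8) { warning("eye aperture clipped to canvas-safe range"); ap <- 1.8 }

  exL <- cx - sp$eyeDist * s / 2; exR <- cx + sp$eyeDist * s / 2
  eyY <- sp$eyeY * s
  ew <- 0.055 * s; eh <- 0.028 * s * ap
  for (ex in c(exL, exR)) {
    eye <- ((X - ex) / ew)^2 + ((Y - eyY) / eh)^2 <= 1
    img[eye] <- sp$featureInt
  }

  browY <- eyY - 0.065 * s - ep$browRaise * s
  bl <- 0.075 * s; bt <- 0.013 * s
  for (sideSign in c(-1, 1)) {
    ex <- if (sideSign < 0) exL else exR
    th <- sideSign * ep$browAngle * pi / 180
    dx <- X - ex; dy <- Y - browY
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    img[abs(u) <= bl & abs(v) <= bt] <- sp$featureInt
  }

  nose <- abs(X - cx) <= 0.013 * s & abs(Y - 0.565 * s) <= 0.07 * s
  img[nose] <- sp$skin - 30

  my <- sp$mouthY * s
  hw <- 0.14 * s
  halfTh <- (0.010 + 0.055 * mo) * s
  u <- (X - cx) / hw
  curveY <- my + ep$mouthCurv * 0.09 * s * (u^2 - 0.5)
  mouth <- abs(u) <= 1 & abs(Y - curveY) <= halfTh
  img[mouth] <- sp$featureInt

  img <- img + illumination[1] * (X / s - 0.5) + illumination[2] * (Y / s - 0.5)
  if (noiseSd > 0) img <- img + stats::rnorm(s * s, sd = noiseSd)
  GrayImage(pmin(pmax(round(img), 0), 255), "uint8")
}

#' Generate a synthetic multi-source face corpus
#'
#' Deterministically (given \code{seed}) creates \code{nSubjects} subjects
#' dealt round-robin across \code{nSources} pseudo-sources, each source
#' carrying its own skin-intensity offset and illumination gradient
#' (emulating corpus heterogeneity), and renders
#' \code{imagesPerClass} images per subject per expression class:
#' nSubjects x 7 x imagesPerClass images in total. Images are written as
#' PNG under \code{dir/SYNTH_<source>/<label>/<subject>_<k>.png} along with
#' \code{catalog.csv}.
#'
#' @param nSubjects number of subjects (default 30).
#' @param imagesPerClass images per subject per class (default 2).
#' @param nSources number of pseudo-sources (default 3).
#' @param seed RNG seed; two runs with the same seed produce byte-identical
#'   catalogs and images.
#' @param dir output directory (created if needed).
#' @param side canvas side in pixels (default 160).
#' @param noiseSd additive noise sd in gray levels (default 4).
#' @param jitterSd expression jitter multiplier (default 1).
#' @return A \linkS4class{FaceCatalog} of the written images.
#' @export
#' @examples
#' \donttest{
#' cat <- generateCorpus(10, 2, 2, seed = 7, dir = tempfile())
#' nSamples(cat)  # 10 * 7 * 2 = 140
#' }
generateCorpus <- function(nSubjects = 30L, imagesPerClass = 2L, nSources = 3L,
                           seed = 42L, dir = tempfile("synth"), side = 160L,
                           noiseSd = 4, jitterSd = 1) {
  if (nSubjects < 1L || imagesPerClass < 1L || nSources < 1L)
    stop("nSubjects, imagesPerClass and nSources must be positive")
  set.seed(seed)
  srcNames <- paste0("SYNTH_", LETTERS[seq_len(nSources)])
  srcSkin <- stats::runif(nSources, -25, 25)
  srcIll <- cbind(stats::runif(nSources, -25, 25),
                  stats::runif(nSources, -12, 12))
  subjIds <- sprintf("s%02d", seq_len(nSubjects))
  subjSrc <- rep_len(seq_len(nSources), nSubjects)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  rows <- vector("list", nSubjects * 7L * imagesPerClass)
  ri <- 0L
  for (si in seq_len(nSubjects)) {
    src <- subjSrc[si]
    sp <- subjectParams(subjIds[si], skinOffset = srcSkin[src])
    for (label in expressionClasses()) {
      outDir <- file.path(dir, srcNames[src], label)
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_len(imagesPerClass)) {
        ep <- expressionParams(label, jitterSd)
        img <- renderFace(sp, ep, side = side, noiseSd = noiseSd,
                          illumination = srcIll[src, ])
        p <- file.path(outDir, sprintf("%s_%d.png", subjIds[si], k))
        writeGrayPNG(img, p)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(path = p, subject_id = subjIds[si],
                                 dataset = srcNames[src], label = label)
      }
    }
  }
  catalog <- FaceCatalog(do.call(rbind, rows))
  writeCatalog(catalog, file.path(dir, "catalog.csv"))
  catalog
}
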