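test_that("structuring element construction follows the shape definitions", {
  expect_equal(sum(seMask(makeStructuringElement("square", 7))), 49)
  expect_equal(sum(seMask(makeStructuringElement("disk", 7))), 29)
  # size-1 elements are the identity for both shapes
  for (shape in c("square", "disk")) {
    se1 <- makeStructuringElement(shape, 1)
    expect_equal(sum(seMask(se1)), 1)
    m <- randomUint8(5, 5)
    expect_equal(dilateImage(m, se1), m)
    expect_equal(erodeImage(m, se1), m)
  }
  # center origin always active
  for (s in c(3, 5, 7)) {
    mask <- seMask(makeStructuringElement("disk", s))
    expect_true(mask[(s + 1) / 2, (s + 1) / 2])
  }
  expect_error(makeStructuringElement("square", 4), "odd")
  expect_error(makeStructuringElement("disk", 0), "odd")
  expect_error(makeStructuringElement("disk", -3), "odd")
})

test_that("dilation and erosion match hand-worked examples", {
  se3 <- makeStructuringElement("square", 3)
  m <- matrix(0, 3, 3); m[2, 2] <- 5
  expect_equal(dilateImage(m, se3), matrix(5, 3, 3))
  expect_equal(erodeImage(m, se3), matrix(0, 3, 3))
  # constant images are fixed points of all four operators
  cimg <- matrix(77, 6, 9)
  for (f in list(dilateImage, erodeImage, openImage, closeImage))
    expect_equal(f(cimg, se3), cimg)
})

test_that("operators match the naive sliding-window oracle bit-exactly", {
  set.seed(101)
  ses <- list(makeStructuringElement("square", 3),
              makeStructuringElement("square", 7),
              makeStructuringElement("disk", 7))
  for (rep in 1:8) {
    m <- randomUint8(sample(5:16, 1), sample(5:16, 1))
    for (se in ses) {
      mask <- seMask(se)
      expect_identical(dilateImage(m, se), oracleDilate(m, mask))
      expect_identical(erodeImage(m, se), oracleErode(m, mask))
      expect_identical(openImage(m, se), oracleOpen(m, mask))
      expect_identical(closeImage(m, se), oracleClose(m, mask))
    }
  }
})

test_that("ordering chain, idempotence and duality hold", {
  set.seed(202)
  se <- makeStructuringElement("disk", 7)
  for (rep in 1:5) {
    m <- randomUint8(12, 12)
    e <- erodeImage(m, se); o <- openImage(m, se)
    cl <- closeImage(m, se); d <- dilateImage(m, se)
    expect_true(all(e <= o), label = "erode <= open")
    expect_true(all(o <= m), label = "open <= image")
    expect_true(all(m <= cl), label = "image <= close")
    expect_true(all(cl <= d), label = "close <= dilate")
    expect_identical(openImage(o, se), o)
    expect_identical(closeImage(cl, se), cl)
    # dual pair under intensity complement (symmetric element)
    expect_identical(erodeImage(m, se), 255 - dilateImage(255 - m, se))
  }
})

test_that("opening removes impulses; closing fills holes", {
  se3 <- makeStructuringElement("square", 3)
  imp <- matrix(0, 7, 7); imp[4, 4] <- 200
  expect_equal(openImage(imp, se3), matrix(0, 7, 7))
  hole <- matrix(255, 7, 7); hole[4, 4] <- 0
  expect_equal(closeImage(hole, se3), matrix(255, 7, 7))
})

test_that("residuals are non-negative, zero on constants, and match the top-hats", {
  se <- makeStructuringElement("disk", 7)
  cimg <- matrix(128, 10, 10)
  rc <- morphResiduals(cimg, se)
  for (ch in c("ifd", "ife", "ifo", "ifc"))
    expect_equal(rc[[ch]], matrix(0, 10, 10))

  se3 <- makeStructuringElement("square", 3)
  m <- matrix(0, 3, 3); m[2, 2] <- 5
  r <- morphResiduals(m, se3)
  expIfd <- matrix(5, 3, 3); expIfd[2, 2] <- 0
  expIfe <- matrix(0, 3, 3); expIfe[2, 2] <- 5
  expect_equal(r$ifd, expIfd)
  expect_equal(r$ife, expIfe)

  set.seed(303)
  for (rep in 1:5) {
    m <- randomUint8(11, 9)
    r <- morphResiduals(m, se)
    mask <- seMask(se)
    expect_true(all(r$ifd >= 0) && all(r$ife >= 0) &&
                  all(r$ifo >= 0) && all(r$ifc >= 0))
    # white / black top-hats computed through the independent oracle
    expect_identical(r$ifo, m - oracleOpen(m, mask))
    expect_identical(r$ifc, oracleClose(m, mask) - m)
    expect_identical(r$ifd, oracleDilate(m, mask) - m)
    expect_identical(r$ife, m - oracleErode(m, mask))
  }
})

test_that("GrayImage methods preserve domain and validity is enforced", {
  g <- GrayImage(matrix(0:24, 5, 5), "uint8")
  se3 <- makeStructuringElement("square", 3)
  d <- dilateImage(g, se3)
  expect_s4_class(d, "GrayImage")
  expect_equal(imageDomain(d), "uint8")
  rs <- morphResiduals(g, se3)
  expect_s4_class(rs, "ResidualSet")
  expect_equal(dim(residualChannel(rs, "Ifd")), dim(g))
  expect_error(GrayImage(matrix(-1, 2, 2), "uint8"), "domain")
  expect_error(GrayImage(matrix(2, 2, 2), "unit"), "domain")
})

test_that("oversized structuring elements warn but still compute", {
  m <- randomUint8(4, 4)
  se <- makeStructuringElement("square", 11)
  expect_warning(d <- dilateImage(m, se), "larger")
  expect_equal(d, matrix(max(m), 4, 4))
})

test_that("stackChannels preserves order and rejects mismatches", {
  a <- matrix(1, 4, 4); b <- matrix(2, 4, 4); c3 <- matrix(3, 4, 4)
  st <- stackChannels(list(If = a, Ife = b, Ifo = c3))
  expect_equal(dim(st), c(4, 4, 3))
  expect_equal(st[, , 1], a)      # channel 0 is the first list element
  expect_equal(dimnames(st)[[3]], c("If", "Ife", "Ifo"))
  one <- stackChannels(list(a))
  expect_equal(one[, , 1], a)
  expect_error(stackChannels(list(a, matrix(1, 3, 4))), "dimensions")
  expect_error(stackChannels(list(GrayImage(a, "uint8"),
                                  GrayImage(a / 10, "unit"))), "domain")
})

test_that("morphChannels maps specifications onto image and residual planes", {
  se <- makeStructuringElement("disk", 7)
  m <- randomUint8(12, 12)
  st <- morphChannels(m, c("If", "Ife", "Ifo"), se)
  r <- morphResiduals(m, se)
  expect_equal(st[, , 1], m)
  expect_equal(st[, , 2], r$ife)
  expect_equal(st[, , 3], r$ifo)
  # replicated grayscale channels for the ablation path
  rep4 <- morphChannels(m, rep("If", 4), se)
  for (k in 1:4) expect_equal(rep4[, , k], m)
  # the dense-only baseline front-end: constant image -> zero residual
  expect_equal(morphChannels(matrix(50, 8, 8), "Ifo", se)[, , 1],
               matrix(0, 8, 8))
  expect_error(morphChannels(m, c("If", "bogus"), se), "channels")
})
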