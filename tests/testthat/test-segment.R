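test_that("edge maps behave on degenerate and step inputs", {
  # constant image: zero gradient everywhere, empty mask, no error
  em <- edge_map(matrix(100, 32, 32))
  expect_true(all(em$mask == 0))

  # vertical step edge: mask concentrated within +-1 of the step column
  img <- cbind(matrix(0, 32, 16), matrix(255, 32, 16))
  em <- edge_map(img, thresh_quantile = 0.5)
  hits <- which(em$mask == 1, arr.ind = TRUE)
  expect_gt(nrow(hits), 0)
  # step boundary between columns 16 and 17 (1-based)
  expect_true(all(hits[, "col"] %in% 15:18))

  expect_error(edge_map(matrix(0, 8, 8)), "too small")
})

test_that("vertical weighting suppresses horizontal edges", {
  # horizontal step (eyelid-like): upweighting the x-derivative must push
  # the horizontal edge below the quantile threshold when vertical
  # structure is present too
  img <- matrix(0, 40, 40)
  img[1:20, ] <- 200                      # horizontal edge at row 20
  img[, 1:10] <- img[, 1:10] + 50         # vertical edge at column 10
  em1 <- edge_map(img, thresh_quantile = 0.6, vertical_weight = 1)
  em8 <- edge_map(img, thresh_quantile = 0.6, vertical_weight = 8)
  share <- function(em) {
    hits <- which(em$mask == 1, arr.ind = TRUE)
    mean(hits[, "row"] %in% 19:22)
  }
  expect_lt(share(em8), share(em1))
})

test_that("accumulator equals the brute-force voter cell-for-cell", {
  set.seed(71)
  h <- 48; w <- 48
  mask <- matrix(0L, h, w)
  mask[sample(h * w, 60)] <- 1L
  mask <- mask | circle_mask(h, w, 23, 25, 12)
  radii <- 10:14
  res <- hough_circles(mask * 1L, c(10, 14))
  oracle <- brute_hough(mask * 1L, radii)
  expect_identical(as.vector(res$accumulator), as.vector(oracle))
  # vote conservation: every edge pixel contributes one vote per in-bounds
  # accumulator cell on each of its circles
  expect_equal(sum(res$accumulator), sum(oracle))
})

test_that("exact circle masks are recovered exactly", {
  mask <- circle_mask(64, 64, yc = 30, xc = 33, r = 20)
  res <- hough_circles(mask, c(15, 25))
  expect_equal(res$circle$xc, 33)
  expect_equal(res$circle$yc, 30)
  expect_equal(res$circle$r, 20)
  # the true cell collects every edge pixel and strictly exceeds all others
  expect_equal(res$votes, sum(mask))
  expect_equal(sum(res$accumulator == res$votes), 1L)
})

test_that("voting is linear: a mask accumulates the sum of its pixels' votes", {
  h <- w <- 40
  set.seed(5)
  pts <- cbind(sample(10:30, 8), sample(10:30, 8))
  mask <- matrix(0L, h, w)
  mask[pts] <- 1L
  res <- hough_circles(mask, c(7, 7))
  single <- Reduce(`+`, lapply(seq_len(nrow(pts)), function(i) {
    m <- matrix(0L, h, w); m[pts[i, 1], pts[i, 2]] <- 1L
    brute_hough(m, 7)
  }))
  expect_identical(as.vector(res$accumulator), as.vector(single))
  # a single pixel's votes lie exactly on the circle around it
  m1 <- matrix(0L, h, w); m1[21, 21] <- 1L
  acc1 <- brute_hough(m1, 7)
  expect_identical(which(acc1[, , 1] > 0),
                   which(circle_mask(h, w, 20, 20, 7) > 0))
})

test_that("radius windows select among concentric circles", {
  mask <- circle_mask(64, 64, 32, 32, 12) | circle_mask(64, 64, 32, 32, 22)
  res <- hough_circles(mask * 1L, c(10, 14))
  expect_equal(res$circle$r, 12)
  expect_equal(c(res$circle$xc, res$circle$yc), c(32, 32))
})

test_that("ties break to the row-major-first center", {
  mask <- circle_mask(64, 64, 15, 15, 8) | circle_mask(64, 64, 45, 45, 8)
  res <- hough_circles(mask * 1L, c(8, 8))
  expect_equal(c(res$circle$yc, res$circle$xc), c(15, 15))
})

test_that("fewer than 8 edge pixels is a segmentation failure", {
  m <- matrix(0L, 32, 32); m[10, 10] <- 1L
  expect_error(hough_circles(m, c(5, 8)), "segmentation failure")
})

test_that("enlarging the radius window never decreases the peak votes", {
  gt <- clean_eye(noise_sigma = 4)
  em <- edge_map(gt$image, 0.97)
  narrow <- hough_circles(em, c(20, 30))
  wide <- hough_circles(em, c(15, 35))
  expect_gte(wide$votes, narrow$votes)
})

test_that("detected centers shift exactly with image translation", {
  gt <- clean_eye(center = c(150, 130))
  img <- gt$image
  dy <- 4; dx <- 6
  shifted <- matrix(220L, nrow(img), ncol(img))
  shifted[(1 + dy):nrow(img), (1 + dx):ncol(img)] <-
    img[1:(nrow(img) - dy), 1:(ncol(img) - dx)]
  s0 <- segment_iris(img)
  s1 <- segment_iris(shifted)
  expect_equal(s1$pupil$xc - s0$pupil$xc, dx)
  expect_equal(s1$pupil$yc - s0$pupil$yc, dy)
  expect_equal(s1$iris$xc - s0$iris$xc, dx)
  expect_equal(s1$iris$yc - s0$iris$yc, dy)
  expect_equal(s1$pupil$r, s0$pupil$r)
  expect_equal(s1$iris$r, s0$iris$r)
})

test_that("clean synthetic eyes are segmented within 2 px", {
  gt <- clean_eye(center = c(160, 140), pr = 25, ir = 70)
  seg <- segment_iris(gt$image)
  expect_lt(abs(seg$pupil$xc - 160) + abs(seg$pupil$yc - 140), 2.001)
  expect_lt(abs(seg$pupil$r - 25), 2.001)
  expect_lt(abs(seg$iris$xc - 160) + abs(seg$iris$yc - 140), 2.001)
  expect_lt(abs(seg$iris$r - 70), 2.001)
  expect_gt(seg$iris_votes, 0)
  # pupil strictly inside iris
  dc <- sqrt((seg$pupil$xc - seg$iris$xc)^2 + (seg$pupil$yc - seg$iris$yc)^2)
  expect_lt(dc + seg$pupil$r, seg$iris$r)
})

test_that("occluded eyes still segment (eyelid edges are suppressed)", {
  spec <- eye_spec(2L, circle(160, 140, 28), circle(160, 140, 72),
                   noise_sigma = 5, occlusion_fraction = 0.25)
  gt <- render_eye(spec)
  seg <- segment_iris(gt$image)
  expect_lt(abs(seg$iris$r - 72), 3.001)
  expect_lt(sqrt((seg$iris$xc - 160)^2 + (seg$iris$yc - 140)^2), 3.001)
})

test_that("blank images raise a segmentation failure", {
  expect_error(segment_iris(matrix(128, 64, 64)), "segmentation failure")
})
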