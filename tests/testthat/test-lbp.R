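# Local binary/ternary pattern operators against brute-force oracles.

test_that("LBP code of the documented 3x3 neighbourhood is 135", {
  # centre 0.5, neighbours (E,NE,N,NW,W,SW,S,SE) = (.9,.9,.9,.1,.1,.1,.1,.9)
  img <- matrix(0, 3, 3)
  img[2, 2] <- 0.5
  img[2, 3] <- 0.9  # E
  img[1, 3] <- 0.9  # NE
  img[1, 2] <- 0.9  # N
  img[1, 1] <- 0.1  # NW
  img[2, 1] <- 0.1  # W
  img[3, 1] <- 0.1  # SW
  img[3, 2] <- 0.1  # S
  img[3, 3] <- 0.9  # SE
  codes <- mrigrade:::lbp_codes(img, lbp_spec(radius = 1, points = 8))
  expect_equal(as.vector(codes), 135)  # bits 1,1,1,0,0,0,0,1
})

test_that("constant images give the all-ones code everywhere", {
  spec <- lbp_spec()
  h <- lbp_histogram(matrix(0.42, 12, 12), spec)
  # all-ones code is uniform with 8 ones -> bin 9 under the uniform-ri map
  expect_equal(h[9], 1)
  expect_equal(sum(h), 1)

  hr <- rlbp_histogram(matrix(0.42, 12, 12), spec, n_radii = 3)
  expect_equal(hr[9], 1)

  lt <- ltp_histograms(matrix(0.42, 12, 12), spec, t = 0.1)
  # upper pattern all-zeros -> bin 1 (zero ones, uniform)
  expect_equal(lt$upper[1], 1)
  # lower pattern all-ones (every neighbour <= centre - t is false... the
  # lower plane thresholds neighbour <= centre - t, none qualify) -> bin 1
  expect_equal(lt$lower[1], 1)
})

test_that("lbp/rlbp/ltp per-pixel codes equal brute-force oracles exactly", {
  spec <- lbp_spec(radius = 1, points = 8)
  for (seed in 1:4) {
    img <- random_image(16, seed + 100)
    expect_identical(as.vector(mrigrade:::lbp_codes(img, spec)),
                     as.vector(oracle_lbp_codes(img, 1, 8)))
    expect_identical(as.vector(mrigrade:::rlbp_codes(img, spec, 3L)),
                     as.vector(oracle_rlbp_codes(img, 3, 8)))
    got <- mrigrade:::ltp_codes(img, spec, 0.1)
    want <- oracle_ltp_codes(img, 0.1, 1, 8)
    expect_identical(as.vector(got$upper), as.vector(want$upper))
    expect_identical(as.vector(got$lower), as.vector(want$lower))
  }
})

test_that("rlbp with one radius reduces to lbp; ltp upper approaches lbp as t -> 0", {
  img <- random_image(16, 7)
  spec <- lbp_spec()
  expect_equal(rlbp_histogram(img, spec, n_radii = 1L), lbp_histogram(img, spec))

  # t -> 0 limit: upper LTP pattern equals the >= threshold LBP pattern on
  # an image with no exact ties
  tiny <- 1e-12
  got <- mrigrade:::ltp_codes(img, spec, tiny)$upper
  expect_equal(as.vector(got), as.vector(mrigrade:::lbp_codes(img, spec)))
})

test_that("ternary coding cases follow the definition and histograms are normalized", {
  # centre 0.5, t = 0.1: neighbour 0.65 -> +1; 0.45 -> 0; 0.30 -> -1
  img <- matrix(0.5, 3, 3)
  img[2, 3] <- 0.65  # E
  img[1, 2] <- 0.45  # N
  img[2, 1] <- 0.30  # W
  cds <- mrigrade:::ltp_codes(img, lbp_spec(), t = 0.1)
  expect_equal(bitwAnd(as.integer(cds$upper), 1L), 1L)        # E bit set in upper
  expect_equal(bitwAnd(as.integer(cds$upper), 4L + 16L), 0L)  # N, W not upper
  expect_equal(bitwAnd(as.integer(cds$lower), 16L), 16L)      # W bit set in lower
  expect_equal(bitwAnd(as.integer(cds$lower), 1L + 4L), 0L)   # E, N not lower

  expect_error(ltp_histograms(img, lbp_spec(), t = 1.5),
               class = "mrigrade_validation_error")
  for (seed in 1:3) {
    im <- random_image(16, seed)
    expect_equal(sum(lbp_histogram(im)), 1, tolerance = 1e-9)
    expect_equal(sum(rlbp_histogram(im)), 1, tolerance = 1e-9)
    hs <- ltp_histograms(im)
    expect_equal(sum(hs$upper), 1, tolerance = 1e-9)
    expect_equal(sum(hs$lower), 1, tolerance = 1e-9)
    expect_true(all(hs$upper >= 0) && all(hs$lower >= 0))
  }
})
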