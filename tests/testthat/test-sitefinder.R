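raw_curve <- function(v, id = "t") distance_curve(v, "ndc", id, smoothed = FALSE)
sm_curve <- function(v, id = "t") distance_curve(v, "ndc", id, smoothed = TRUE)

test_that("gaussian smoothing: constant identity, sigma 0, kernel oracle", {
  const <- raw_curve(rep(5, 30))
  for (sg in c(0.5, 1, 2, 7))
    expect_equal(gaussian_smooth(const, sigma = sg)$values, rep(5, 30))

  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  s0 <- gaussian_smooth(raw_curve(v), sigma = 0)
  expect_equal(s0$values, v)
  expect_true(s0$smoothed)

  imp <- c(rep(0, 10), 1, rep(0, 10))
  got <- gaussian_smooth(raw_curve(imp), sigma = 1.5)$values
  expect_lt(max(abs(got - oracle_smooth(imp, 1.5))), 1e-9)
})

test_that("boundary modes match the oracle on asymmetric signals", {
  set.seed(21)
  v <- cumsum(stats::runif(40))  # trending signal stresses the edges
  for (b in c("reflect", "nearest")) {
    got <- gaussian_smooth(raw_curve(v), sigma = 3, boundary = b)$values
    expect_lt(max(abs(got - oracle_smooth(v, 3, boundary = b))), 1e-9)
  }
})

test_that("smoothing config and state are validated", {
  expect_error(gaussian_smooth(raw_curve(1:5), sigma = -1),
               class = "rnasites_config_error")
  sm <- gaussian_smooth(raw_curve(1:5 + 0), sigma = 1)
  expect_error(gaussian_smooth(sm, sigma = 1), "already")
})

test_that("extreme points: interior, endpoints, plateaus", {
  expect_equal(find_extrema(sm_curve(c(1, 2, 3, 2, 1))), c(1L, 3L, 5L))
  expect_equal(find_extrema(sm_curve(c(1, 2, 3, 2, 1)),
                            include_endpoints = FALSE), 3L)
  expect_equal(find_extrema(sm_curve(1:10)), c(1L, 10L))
  expect_equal(find_extrema(sm_curve(1:10), include_endpoints = FALSE),
               integer(0))
  expect_equal(find_extrema(sm_curve(rep(2, 8))), integer(0))
  # odd plateau -> its midpoint; even plateau -> lower middle
  expect_equal(find_extrema(sm_curve(c(1, 5, 5, 5, 1)),
                            include_endpoints = FALSE), 3L)
  expect_equal(find_extrema(sm_curve(c(1, 5, 5, 5, 5, 1)),
                            include_endpoints = FALSE), 3L)
  # minima count too
  expect_equal(find_extrema(sm_curve(c(5, 1, 5)), include_endpoints = FALSE),
               2L)
})

test_that("extrema land within 1 nt of the analytic positions of a sinusoid", {
  i <- 1:60
  v <- 2 + sin(2 * pi * i / 20)
  got <- find_extrema(sm_curve(v), include_endpoints = FALSE)
  analytic <- c(5, 15, 25, 35, 45, 55)  # peaks then troughs, period 20
  expect_equal(length(got), length(analytic))
  expect_true(all(abs(got - analytic) <= 1))
})

test_that("extrema alternate max/min and survive affine value changes", {
  set.seed(22)
  for (rep in 1:20) {
    v <- as.numeric(sample(0:9, 60, replace = TRUE))
    pos <- find_extrema(sm_curve(v), include_endpoints = FALSE)
    if (length(pos) > 1) {
      # alternation: neighbouring extrema are max,min,max,... so their
      # values must strictly alternate in direction
      vals <- v[pos]
      expect_true(all(diff(vals) != 0))
      if (length(pos) > 2)
        expect_true(all(diff(sign(diff(vals))) != 0))
    }
    expect_equal(find_extrema(sm_curve(v + 7.5)), find_extrema(sm_curve(v)))
    expect_equal(find_extrema(sm_curve(v * 3.2)), find_extrema(sm_curve(v)))
  }
})

test_that("merging chains nearby extrema into disjoint sites", {
  expect_equal(merge_points(c(10L, 11L, 14L), n = 20)$sites$start, c(10L, 14L))
  expect_equal(merge_points(c(10L, 11L, 14L), n = 20)$sites$end, c(11L, 14L))
  one <- merge_points(c(10L, 12L, 14L), n = 20)
  expect_equal(nrow(one$sites), 1L)
  expect_equal(one$sites$start, 10L)
  expect_equal(one$sites$end, 14L)
  # adjacent pair merges into a single 2-nt site
  pair <- merge_points(c(75L, 76L), n = 76)
  expect_equal(nrow(pair$sites), 1L)
  expect_equal(c(pair$sites$start, pair$sites$end), c(75L, 76L))
  expect_error(merge_points(c(5L, 30L), n = 20), "outside")
  expect_error(merge_points(c(5L, 5L), n = 20), "increasing")
})

test_that("site peaks take the most extreme smoothed value, ties to the left", {
  v <- rep(1, 20); v[10] <- 4; v[12] <- 9
  ss <- merge_points(c(10L, 12L), n = 20, values = v)
  expect_equal(ss$sites$peak_position, 12L)
  expect_equal(ss$sites$peak_value, 9)
  vt <- rep(1, 20); vt[10] <- 9; vt[12] <- 9
  expect_equal(merge_points(c(10L, 12L), n = 20,
                            values = vt)$sites$peak_position, 10L)
})

test_that("prediction pipeline: constant geometry yields no sites", {
  th <- 2 * pi * (0:39) / 40
  circle <- cbind(cos(th), sin(th))
  ss <- predict_sites(circle, metric = "ndc")
  expect_equal(nrow(ss$sites), 0L)
})

test_that("planted lobes are recovered as distinct sites", {
  pl <- make_planted_curve(100, positions = 50, amplitudes = 3)
  ss <- predict_sites(pl$curve, sigma = 2)
  interior <- ss$sites[ss$sites$peak_position %in% 2:99, ]
  expect_equal(nrow(interior), 1L)
  expect_lte(abs(interior$peak_position - 50), 1)

  p2 <- make_planted_curve(120, positions = c(40, 70), amplitudes = c(3, -2))
  ss2 <- predict_sites(p2$curve, sigma = 2)
  interior2 <- ss2$sites[ss2$sites$peak_position %in% 2:119, ]
  expect_equal(nrow(interior2), 2L)
  expect_true(all(abs(sort(interior2$peak_position) - c(40, 70)) <= 1))
})

test_that("stronger smoothing never adds interior extrema on planted fixtures", {
  pl <- make_planted_curve(150, positions = c(40, 75, 110),
                           amplitudes = c(3, -2, 2.5))
  counts <- vapply(c(0.5, 1, 2, 4), function(sg) {
    sm <- gaussian_smooth(pl$curve, sigma = sg)
    length(find_extrema(sm, include_endpoints = FALSE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the pipeline is deterministic end to end", {
  s <- make_structure("cloverleaf")
  a <- predict_sites(s)
  b <- predict_sites(s)
  expect_identical(a$sites, b$sites)
  expect_identical(attr(a, "curve")$values, attr(b, "curve")$values)
})
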