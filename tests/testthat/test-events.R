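test_that("interval IoU matches hand-computed interval arithmetic", {
  expect_equal(interval_iou(wseg(160, 5), wseg(160, 5)), 1)
  # E1 = [157.5, 162.5], E2 = [159.5, 164.5]: 3 / 7
  expect_equal(interval_iou(wseg(160, 5), wseg(162, 5)), 3 / 7)
  expect_equal(interval_iou(wseg(100, 5), wseg(300, 5)), 0)
  # zero-width conventions
  expect_equal(interval_iou(wseg(160, 0), wseg(160, 0)), 1)
  expect_equal(interval_iou(wseg(160, 0), wseg(161, 0)), 0)
})

test_that("Bhattacharyya closed form matches printed-formula examples", {
  id <- bhattacharyya_distance(160, 5, 160, 5)
  expect_equal(id$distance, 0)
  expect_equal(id$coefficient, 1)
  ex1 <- bhattacharyya_distance(160, 5, 162, 5)
  expect_equal(ex1$distance, 0.25 * 4 / 50, tolerance = 1e-12)   # 0.02
  expect_equal(ex1$coefficient, exp(-0.02), tolerance = 1e-12)   # 0.9802
  ex2 <- bhattacharyya_distance(100, 1, 100, 10)
  expect_equal(ex2$distance, 0.5 * log(101 / 20), tolerance = 1e-12)
  expect_equal(round(ex2$coefficient, 3), 0.445)
  expect_error(bhattacharyya_distance(100, 0, 100, 1), "positive")
})

test_that("coefficient equals the overlap-integral oracle on random pairs", {
  set.seed(17)
  for (i in 1:50) {
    mu1 <- runif(1, 50, 500); mu2 <- mu1 + rnorm(1, 0, 10)
    s1 <- runif(1, 0.5, 10); s2 <- runif(1, 0.5, 10)
    bc <- bhattacharyya_distance(mu1, s1, mu2, s2)
    expect_equal(bc$coefficient, bc_integral_oracle(mu1, s1, mu2, s2),
                 tolerance = 1e-6)
  }
})

test_that("regroup implements inverse-variance statistics (both forms)", {
  single <- regroup(160, 5)
  expect_equal(single$mu, 160)
  expect_equal(single$sigma, 5)
  rg <- regroup(c(160, 162), c(5, 5))
  expect_equal(rg$mu, 161)
  expect_equal(rg$sigma, sqrt(1 / (2 / 25)), tolerance = 1e-12)   # 3.536
  printed <- regroup(c(160, 162), c(5, 5), sigma_as_printed = TRUE)
  expect_equal(printed$sigma, sqrt(2 / 25), tolerance = 1e-12)    # 0.283
  expect_error(regroup(c(160, 170), c(5, 0)), "positive")
})

test_that("corrected sigma shrinks below min member sigma; printed grows", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    mus <- runif(n, 50, 500); sigmas <- runif(n, 1, 8)
    expect_lt(regroup(mus, sigmas)$sigma, min(sigmas))
    if (n >= 2) {
      expect_gt(regroup(mus, sigmas, sigma_as_printed = TRUE)$sigma,
                1 / max(sigmas))
    }
  }
  # printed sigma grows with member count for identical members
  s3 <- regroup(rep(160, 3), rep(2, 3), sigma_as_printed = TRUE)$sigma
  s6 <- regroup(rep(160, 6), rep(2, 6), sigma_as_printed = TRUE)$sigma
  expect_gt(s6, s3)
})

test_that("aggregation merges adjacent compatible segments, splits others", {
  # compatible pair: IoU = 4/6, coeff exp(-0.005) -> one event
  ev <- aggregate_segments(list(wseg(160, 5, 0), wseg(161, 5, 1)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_segments, 2)
  expect_equal(ev$start_s, 0); expect_equal(ev$end_s, 2)
  # disjoint intervals -> two events
  ev2 <- aggregate_segments(list(wseg(160, 5, 0), wseg(300, 5, 1)))
  expect_equal(nrow(ev2), 2)
  # three chained segments -> one 3-segment event
  ev3 <- aggregate_segments(list(wseg(160, 5, 0), wseg(161, 5, 1),
                                 wseg(162, 5, 2)))
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$n_segments, 3)
  # non-adjacent indices never merge even with identical stats
  ev4 <- aggregate_segments(list(wseg(160, 5, 0), wseg(160, 5, 2)))
  expect_equal(nrow(ev4), 2)
})

test_that("single-segment events keep their own statistics", {
  ev <- aggregate_segments(list(wseg(213.7, 3.1, 5)))
  expect_equal(ev$mu_f0, 213.7)
  expect_equal(ev$sigma_f0, 3.1)
  expect_equal(ev$start_s, 5); expect_equal(ev$end_s, 6)
})

test_that("voiced-frame count is conserved through merging", {
  segs <- list(wseg(160, 5, 0, 12L), wseg(161, 5, 1, 9L), wseg(300, 4, 2, 7L))
  ev <- aggregate_segments(segs)
  expect_equal(sum(ev$n_voiced), 12L + 9L + 7L)
})

test_that("event count is monotone non-increasing in the BC threshold", {
  set.seed(41)
  segs <- lapply(0:19, function(i) {
    wseg(150 + cumsum(rnorm(20, 0, 2))[i + 1], runif(1, 1.5, 6), i)
  })
  counts <- vapply(c(0.2, 0.5, 0.7, 0.9, 0.99), function(th) {
    nrow(aggregate_segments(segs, bc_threshold = th))
  }, numeric(1))
  expect_false(is.unsorted(counts))
})

test_that("bc_as_printed thresholds the distance instead of the coefficient", {
  # distance 0.02 < 0.7 -> literal reading refuses the merge
  ev <- aggregate_segments(list(wseg(160, 5, 0), wseg(161, 5, 1)),
                           bc_as_printed = TRUE)
  expect_equal(nrow(ev), 2)
  # very dissimilar sigmas give a large distance (0.81) while IoU still
  # touches 0.1 -> literal reading merges
  s <- list(wseg(160, 10, 0), wseg(160, 1, 1))
  expect_equal(nrow(aggregate_segments(s, bc_as_printed = TRUE)), 1)
})

test_that("period aggregation sums counts and masses on half-open periods", {
  periods <- data.frame(
    period_id = c("p1", "p2"),
    start = as.POSIXct(c("2024-06-17 00:00", "2024-06-18 00:00"), tz = "UTC"),
    end = as.POSIXct(c("2024-06-18 00:00", "2024-06-19 00:00"), tz = "UTC"))
  rec_start <- as.POSIXct("2024-06-17 10:00", tz = "UTC")
  events <- data.frame(start_s = c(0, 10, 20, 50400), mass_mg = c(10, 10, 10, 5))
  agg <- aggregate_period(events, periods, rec_start)
  expect_equal(agg$count, c(3L, 1L))
  expect_equal(agg$biomass_g, c(0.030, 0.005))
  # boundary event belongs to the later period
  boundary <- data.frame(start_s = 14 * 3600, mass_mg = 2)   # exactly midnight
  agg2 <- aggregate_period(boundary, periods, rec_start)
  expect_equal(agg2$count, c(0L, 1L))
  # outside all periods -> dropped with warning
  outside <- data.frame(start_s = 10 * 24 * 3600, mass_mg = 1)
  expect_warning(agg3 <- aggregate_period(outside, periods, rec_start),
                 "dropped")
  expect_equal(sum(agg3$count), 0L)
  # empty events
  empty <- aggregate_period(events[0, ], periods, rec_start)
  expect_equal(empty$count, c(0L, 0L))
  expect_equal(empty$biomass_g, c(0, 0))
})
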