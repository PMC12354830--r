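test_that("region boundaries follow the <=240 / (240,340] / >340 partition", {
  expect_equal(region_of(240), "dense")
  expect_equal(region_of(300), "less_dense")
  expect_equal(region_of(340), "less_dense")
  expect_equal(region_of(340.001), "sparse")
  expect_equal(region_of(480), "sparse")
  expect_equal(region_of(c(100, 250, 500)),
               c("dense", "less_dense", "sparse"))
})

test_that("reference table loads, validates, and caches fallbacks", {
  tab <- load_reference_table(crafted_table_df())
  expect_s3_class(tab, "reference_table")
  expect_equal(sum(tab$region == "dense"), 10)
  expect_equal(sum(tab$region == "less_dense"), 5)
  expect_equal(sum(tab$region == "sparse"), 5)
  expect_equal(attr(tab, "mass_480"), 2)
  bad <- crafted_table_df(); bad$mass_mg[3] <- 0
  expect_error(load_reference_table(bad), "row")
  nomass <- crafted_table_df(); nomass$mass_mg <- NULL
  expect_error(load_reference_table(nomass), "mass_mg")
})

test_that("synthetic table fixture round-trips through CSV", {
  df <- synth_reference_table(40, 6, 4, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  tab <- load_reference_table(tmp)
  expect_equal(nrow(tab), 50)
  expect_equal(sum(tab$region == "dense"), 40)
  expect_true(any(tab$wbf_hz == 480))
  expect_true(all(tab$obs_prob == 1))
})

test_that("candidate window grows by 0.5 Hz and respects the cap", {
  tab <- load_reference_table(data.frame(
    taxon = c("a", "b"), wbf_hz = c(97.2, 103), mass_mg = c(1, 2),
    in_europe = TRUE, obs_prob = 1))
  # entry 2.8 Hz away is first captured at half-width 3.0; the 3.0 Hz-away
  # entry sits exactly on the boundary and is excluded (open window)
  found <- find_candidates(100, 4, tab)
  expect_equal(found$half_width, 3)
  expect_equal(found$candidates$taxon, "a")
  # exact match short-circuits at half-width 0
  exact <- find_candidates(103, 4, tab)
  expect_equal(exact$half_width, 0)
  expect_equal(exact$candidates$taxon, "b")
  # nothing within max(10, sigma)/2
  far <- find_candidates(600, 4, tab)
  expect_equal(nrow(far$candidates), 0)
  expect_true(is.na(far$half_width))
  # a large sigma widens the cap: max(10, 30)/2 = 15
  wide <- find_candidates(112, 30, tab)
  expect_equal(wide$candidates$taxon, "b")
})

test_that("candidate set is monotone in half-width, smallest window returned", {
  tab <- load_reference_table(crafted_table_df())
  set.seed(13)
  for (i in 1:25) {
    mu <- runif(1, 60, 600); sigma <- runif(1, 0.5, 20)
    found <- find_candidates(mu, sigma, tab)
    if (!is.na(found$half_width) && found$half_width > 0) {
      # no candidate at any smaller half-width step
      prev <- found$half_width - 0.5
      if (prev > 0) {
        expect_equal(sum(abs(tab$wbf_hz - mu) < prev), 0)
      }
      expect_gt(nrow(found$candidates), 0)
    }
  }
})

test_that("estimate_mass agrees with the brute-force oracle on every branch", {
  df <- crafted_table_df()
  tab <- load_reference_table(df)
  cases <- list(
    list(mu = 150, sigma = 2),     # exact single match (dense)
    list(mu = 100, sigma = 2),     # exact multiple -> Europe -> weighted
    list(mu = 120, sigma = 2),     # 3 candidates -> 1 European left
    list(mu = 206, sigma = 4),     # window match, single candidate
    list(mu = 228.4, sigma = 1),   # window -> single non-European candidate
    list(mu = 60, sigma = 2),      # dense miss -> dense median
    list(mu = 323, sigma = 1),     # less-dense: window reaches the 320 entry
    list(mu = 278, sigma = 1),     # less-dense miss -> own-region median
    list(mu = 600, sigma = 2),     # sparse miss -> 480 Hz mosquito mass
    list(mu = 480, sigma = 2),     # exact sparse
    list(mu = 300, sigma = 2)      # 2 candidates, both non-European -> 0
  )
  methods_seen <- character()
  for (cs in cases) {
    est <- estimate_mass(cs$mu, cs$sigma, tab)
    expect_equal(est$mass_mg, mass_oracle(cs$mu, cs$sigma, df),
                 info = sprintf("mu=%g sigma=%g", cs$mu, cs$sigma))
    methods_seen <- c(methods_seen, est$method)
  }
  expect_setequal(unique(methods_seen),
                  c("exact", "window", "weighted", "fallback_median",
                    "fallback_480", "zero"))
  # alternative reading: less-dense misses fall back to the dense median
  alt <- estimate_mass(278, 1, tab, fallback_dense_median = TRUE)
  expect_equal(alt$mass_mg, stats::median(df$mass_mg[df$wbf_hz <= 240]))
})

test_that("mass estimates are invariant to table row order", {
  df <- crafted_table_df()
  set.seed(19)
  shuffled <- load_reference_table(df[sample.int(nrow(df)), ])
  tab <- load_reference_table(df)
  for (mu in c(100, 120, 205, 60, 278, 600, 480)) {
    expect_equal(estimate_mass(mu, 2, shuffled)$mass_mg,
                 estimate_mass(mu, 2, tab)$mass_mg)
  }
})

test_that("weighted average reduces to the mean under placeholder obs_prob", {
  df <- data.frame(taxon = c("a", "b"), wbf_hz = c(100, 100.2),
                   mass_mg = c(10, 30), in_europe = TRUE, obs_prob = 1)
  est <- estimate_mass(100.1, 3, load_reference_table(df))
  expect_equal(est$mass_mg, 20)
  expect_equal(est$method, "weighted")
  df$obs_prob <- c(0.9, 0.1)
  est2 <- estimate_mass(100.1, 3, load_reference_table(df))
  expect_equal(est2$mass_mg, 0.9 * 10 + 0.1 * 30)
})

test_that("sparse fallback without a sparse entry is a configuration error", {
  df <- crafted_table_df()[1:15, ]     # dense + less dense only
  tab <- load_reference_table(df)
  expect_error(estimate_mass(600, 2, tab), "480")
})

test_that("WBF-mass correlation: perfect line, null shuffle, errors", {
  line <- data.frame(taxon = letters[1:10], wbf_hz = seq(50, 500, length.out = 10),
                     mass_mg = 100 - 0.15 * seq(50, 500, length.out = 10),
                     in_europe = TRUE, obs_prob = 1)
  ct <- wbf_mass_correlation(load_reference_table(line))
  expect_equal(ct$r, -1, tolerance = 1e-10)
  set.seed(29)
  big <- synth_reference_table(200, 10, 20, seed = 5)
  shuf <- big; shuf$mass_mg <- sample(shuf$mass_mg)
  ct2 <- wbf_mass_correlation(load_reference_table(shuf))
  expect_lt(abs(ct2$r), 0.2)
  const <- line; const$mass_mg <- 5
  expect_error(wbf_mass_correlation(load_reference_table(const)), "constant")
})
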