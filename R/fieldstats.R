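# Field-validation statistics: rank correlation between two monitoring
# series (e.g. sensor counts vs Malaise-trap counts per trapping period),
# Fisher r-to-z comparison of two correlation coefficients, and the OLS
# slope used to describe the scaling between methods.

#' Paired validation series
#'
#' @param values_a,values_b per-period measurements (counts or biomass)
#'   from two monitoring methods, same length.
#' @param period_ids optional period identifiers.
#' @return a `validation_series` data frame.
#' @export
validation_series <- function(values_a, values_b,
                              period_ids = seq_along(values_a)) {
  stopifnot(length(values_a) == length(values_b),
            length(period_ids) == length(values_a))
  structure(data.frame(period_id = period_ids, values_a = values_a,
                       values_b = values_b),
            class = c("validation_series", "data.frame"))
}

#' Spearman rank correlation between two monitoring series
#'
#' Average ranks for ties; two-tailed p-value from the t approximation
#' (`exact = TRUE` switches to the exact permutation null, feasible for
#' small n without ties).
#'
#' @param series a [validation_series] (n >= 4).
#' @param exact use the exact p-value computation.
#' @return list with `rho` and `p_value`.
#' @export
spearman <- function(series, exact = FALSE) {
  stopifnot(inherits(series, "validation_series"), nrow(series) >= 4)
  if (stats::sd(series$values_a) == 0 || stats::sd(series$values_b) == 0) {
    stop("Spearman correlation undefined for a constant series",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(series$values_a, series$values_b, method = "spearman",
                    exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(rho_1) - atanh(rho_2)) / sqrt(1/(n_1-3) + 1/(n_2-3))`,
#' two-tailed normal p-value. Used to compare the sensor-sensor agreement
#' against the trap-trap agreement computed over the same trapping
#' periods; the mild dependence between the two coefficients is ignored,
#' matching the standard independent-samples test.
#'
#' @param rho_1,rho_2 the two correlation coefficients (|rho| < 1).
#' @param n_1,n_2 their sample sizes (> 3).
#' @return list with `rho_1`, `n_1`, `rho_2`, `n_2`, `z_score`, `p_value`.
#' @export
fisher_z_compare <- function(rho_1, n_1, rho_2, n_2 = n_1) {
  if (abs(rho_1) >= 1 || abs(rho_2) >= 1) {
    stop("Fisher transform undefined at |rho| = 1", call. = FALSE)
  }
  stopifnot(n_1 > 3, n_2 > 3)
  z <- (atanh(rho_1) - atanh(rho_2)) / sqrt(1 / (n_1 - 3) + 1 / (n_2 - 3))
  structure(list(rho_1 = rho_1, n_1 = n_1, rho_2 = rho_2, n_2 = n_2,
                 z_score = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "<correlation_comparison> rho %.3f (n=%d) vs %.3f (n=%d): Z = %.3f, P = %.3f\n",
    x$rho_1, x$n_1, x$rho_2, x$n_2, x$z_score, x$p_value))
  invisible(x)
}

#' OLS slope of one monitoring series on the other
#'
#' Regresses `values_a` on `values_b` and returns the slope with its
#' two-tailed t-test p-value.
#'
#' @param series a [validation_series] (n >= 3).
#' @return list with `beta`, `p_value`, `intercept`.
#' @export
ols_slope <- function(series) {
  stopifnot(inherits(series, "validation_series"), nrow(series) >= 3)
  if (stats::sd(series$values_b) == 0) {
    stop("OLS slope undefined: zero variance in predictor", call. = FALSE)
  }
  fit <- stats::lm(values_a ~ values_b, data = series)
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["values_b", "Estimate"]),
       p_value = unname(sm["values_b", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}

#' Shapiro-Wilk normality check (advisory)
#'
#' The pipeline always reports Spearman statistics regardless of the
#' outcome; this is available for data description only.
#'
#' @param values numeric vector (3 <= n <= 5000).
#' @return list with `W` and `p_value`.
#' @export
normality_check <- function(values) {
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p_value = st$p.value)
}

#' Full paired-validation report
#'
#' Computes, for paired per-period tables of two sensors and two traps,
#' the cross-method Spearman correlations and OLS slopes per site and the
#' Fisher r-to-z comparison of sensor-sensor vs trap-trap consistency.
#'
#' @param pairs data frame with columns `period_id`, `sensor1`, `sensor2`,
#'   `malaise1`, `malaise2` (counts or grams for one quantity).
#' @return nested list mirroring the per-site scatter statistics and the
#'   consistency comparison.
#' @export
validation_report <- function(pairs) {
  needed <- c("sensor1", "sensor2", "malaise1", "malaise2")
  stopifnot(all(needed %in% names(pairs)))
  site <- function(a, b) {
    s <- validation_series(a, b)
    c(spearman(s), ols_slope(s))
  }
  ss <- spearman(validation_series(pairs$sensor1, pairs$sensor2))
  mm <- spearman(validation_series(pairs$malaise1, pairs$malaise2))
  list(
    site1 = site(pairs$sensor1, pairs$malaise1),
    site2 = site(pairs$sensor2, pairs$malaise2),
    sensor_sensor = ss,
    malaise_malaise = mm,
    consistency = fisher_z_compare(ss$rho, nrow(pairs), mm$rho, nrow(pairs))
  )
}
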