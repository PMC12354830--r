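# WBF -> body-mass estimation against a literature reference table. The
# table is partitioned into a dense (<= 240 Hz), less dense (240-340 Hz)
# and sparse (> 340 Hz) region by candidate ambiguity; the lookup widens a
# +/- 0.5 Hz window around the estimated WBF until candidates appear or a
# cap of max(10, sigma_f0)/2 Hz is hit, then resolves multiplicity via the
# Europe presence flag and observation-probability weighting.

#' Classify a WBF into the reference-table region
#'
#' @param wbf_hz wing-beat frequency in Hz (vectorized).
#' @return character: "dense" (<= 240), "less_dense" ((240, 340\]) or
#'   "sparse" (> 340).
#' @export
region_of <- function(wbf_hz) {
  stopifnot(all(wbf_hz > 0))
  ifelse(wbf_hz <= 240, "dense",
         ifelse(wbf_hz <= 340, "less_dense", "sparse"))
}

#' Load a WBF-to-body-mass reference table
#'
#' Expected CSV columns: `taxon`, `wbf_hz`, `mass_mg`, `in_europe`
#' (logical or 0/1), `obs_prob` (optional, defaults to the placeholder 1).
#' Region labels and the fallback values (per-region mass medians and the
#' mass of the entry nearest 480 Hz used for sparse-region misses) are
#' cached on load.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return a `reference_table`: the validated data frame with a `region`
#'   column and attributes `median_mass` (named, per region) and
#'   `mass_480`.
#' @export
load_reference_table <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("taxon", "wbf_hz", "mass_mg", "in_europe")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("reference table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"obs_prob" %in% names(df)) df$obs_prob <- 1
  bad <- which(!(df$wbf_hz > 0) | !(df$mass_mg > 0))
  if (length(bad) > 0) {
    stop("non-positive wbf_hz or mass_mg in reference table row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_p <- which(df$obs_prob < 0 | df$obs_prob > 1)
  if (length(bad_p) > 0) {
    stop("obs_prob outside [0, 1] in reference table row(s) ",
         paste(bad_p, collapse = ", "), call. = FALSE)
  }
  df$in_europe <- as.logical(df$in_europe)
  df$region <- region_of(df$wbf_hz)
  medians <- vapply(c(dense = "dense", less_dense = "less_dense",
                      sparse = "sparse"),
                    function(r) {
                      m <- df$mass_mg[df$region == r]
                      if (length(m) > 0) stats::median(m) else NA_real_
                    }, numeric(1))
  mass_480 <- if (any(df$region == "sparse")) {
    sp <- df[df$region == "sparse", ]
    sp$mass_mg[which.min(abs(sp$wbf_hz - 480))]
  } else NA_real_
  structure(df, class = c("reference_table", "data.frame"),
            median_mass = medians, mass_480 = mass_480)
}

#' Find reference-table candidates for an estimated WBF
#'
#' Exact matches (within 0.01 Hz; float equality is meaningless on a
#' continuous axis) are returned at half-width 0. Otherwise the window
#' around `mu_f0` grows in 0.5 Hz steps while the half-width stays within
#' the cap `max(10, sigma_f0)/2`; the first non-empty window wins.
#'
#' @param mu_f0 estimated WBF mean in Hz.
#' @param sigma_f0 estimated WBF standard deviation in Hz (an event's
#'   regrouped sigma).
#' @param table a [load_reference_table()] result.
#' @param exact_tol tolerance for "exact" matches in Hz.
#' @return list with `candidates` (data frame, possibly empty) and
#'   `half_width` (Hz; NA when nothing was found within the cap).
#' @export
find_candidates <- function(mu_f0, sigma_f0, table, exact_tol = 0.01) {
  stopifnot(inherits(table, "reference_table"))
  dist <- abs(table$wbf_hz - mu_f0)
  exact <- dist < exact_tol
  if (any(exact)) {
    return(list(candidates = table[exact, , drop = FALSE], half_width = 0))
  }
  cap <- max(10, sigma_f0) / 2
  half <- 0.5
  while (half <= cap + 1e-9) {
    hit <- dist < half               # open window: boundary entries wait
    if (any(hit)) {                  # for the next 0.5 Hz step
      return(list(candidates = table[hit, , drop = FALSE],
                  half_width = half))
    }
    half <- half + 0.5
  }
  list(candidates = table[integer(0), , drop = FALSE], half_width = NA_real_)
}

#' Estimate body mass for an event's WBF statistics
#'
#' Resolution order: no candidate within the cap -> region fallback
#' (dense and less-dense regions use their own mass median, sparse uses
#' the mass of the entry nearest 480 Hz, i.e. a mosquito); one candidate
#' -> its mass; several -> filter by European presence, then 0 left ->
#' mass 0, 1 left -> its mass, several left -> observation-probability
#' weighted average of their masses (arithmetic mean under the
#' placeholder obs_prob = 1).
#'
#' @param mu_f0,sigma_f0 event WBF statistics (regrouped, Hz).
#' @param table a [load_reference_table()] result.
#' @param fallback_dense_median use the dense-region median for
#'   less-dense-region misses instead of the less-dense region's own
#'   median (alternative published reading).
#' @return a `biomass_estimate` list: `mass_mg`, `region`, `method`
#'   (exact | window | fallback_median | fallback_480 | weighted | zero),
#'   `n_candidates_initial`, `n_candidates_after_europe`, `half_width`.
#' @export
estimate_mass <- function(mu_f0, sigma_f0, table,
                          fallback_dense_median = FALSE) {
  stopifnot(inherits(table, "reference_table"))
  region <- region_of(mu_f0)
  found <- find_candidates(mu_f0, sigma_f0, table)
  cand <- found$candidates
  n0 <- nrow(cand)
  res <- function(mass, method, n_eu = NA_integer_) {
    structure(list(mass_mg = mass, region = region, method = method,
                   n_candidates_initial = n0,
                   n_candidates_after_europe = n_eu,
                   half_width = found$half_width),
              class = "biomass_estimate")
  }
  if (n0 == 0) {
    if (region == "sparse") {
      m <- attr(table, "mass_480")
      if (is.na(m)) {
        stop("reference table has no sparse-region entry for the 480 Hz ",
             "fallback", call. = FALSE)
      }
      return(res(m, "fallback_480"))
    }
    med_region <- if (region == "less_dense" && fallback_dense_median)
      "dense" else region
    m <- attr(table, "median_mass")[[med_region]]
    if (is.na(m)) {
      stop("reference table has no entries in the ", med_region,
           " region for the median fallback", call. = FALSE)
    }
    return(res(m, "fallback_median"))
  }
  if (n0 == 1) {
    return(res(cand$mass_mg, if (found$half_width == 0) "exact" else "window"))
  }
  eu <- cand[cand$in_europe, , drop = FALSE]
  n_eu <- nrow(eu)
  if (n_eu == 0) return(res(0, "zero", n_eu))
  if (n_eu == 1) return(res(eu$mass_mg, "window", n_eu))
  wts <- eu$obs_prob
  if (sum(wts) <= 0) return(res(0, "zero", n_eu))
  res(sum(eu$mass_mg * wts) / sum(wts), "weighted", n_eu)
}

#' Pearson correlation between WBF and body mass across the table
#'
#' @param table a [load_reference_table()] result (>= 3 entries).
#' @return list with `r` and `p_value` (two-tailed).
#' @export
wbf_mass_correlation <- function(table) {
  stopifnot(inherits(table, "reference_table"), nrow(table) >= 3)
  if (stats::sd(table$wbf_hz) == 0 || stats::sd(table$mass_mg) == 0) {
    stop("correlation undefined: constant column", call. = FALSE)
  }
  ct <- stats::cor.test(table$wbf_hz, table$mass_mg, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
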