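#' @title Depth-zoned sea-ice / blue-carbon correlation analysis
#'
#' @description
#' The coastal Antarctic seabed shows a depth-structured relationship
#' between fast-ice duration and benthic blue-carbon stocks: positive in the
#' scour-dominated shallows (longer fast ice shields the seabed from
#' icebergs), no net relationship at 10-40 m where shielding and shortened
#' phytoplankton blooms roughly cancel, negative at typical shelf depths
#' (200-500 m) where keels rarely reach and the bloom effect dominates, and
#' a data-poor "zone of ignorance" at 40-200 m. These functions classify
#' depths into those zones, run per-zone Pearson correlations, and fit the
#' negative fast-ice versus scour-frequency relationship seen in shallow
#' monitoring records.
#'
#' @name zone_analysis
NULL

#' Pearson product-moment correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] that degrades gracefully: a
#' zero-variance input yields an undefined (flagged) result instead of an
#' error.
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return List: `r`, `p` (two-sided, exact t transform on n - 2 df), `n`,
#'   `defined` (FALSE when either input has zero variance).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("pearson() needs at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

#' Classify a depth into the correlation zone scheme
#'
#' Half-open bands, lower bound inclusive: A `[0, 10)`, B `[10, 40)`,
#' ignorance `[40, 200)`, C `[200, 500)`, D `[500, 1000]`. Depths beyond
#' 1000 m fall outside the analysed range.
#'
#' @param depth Numeric depth(s) in metres, >= 0.
#' @param bounds Named numeric vector of zone breakpoints
#'   (`a_b`, `b_ign`, `ign_c`, `c_d`, `max`), overridable.
#' @return Character vector of zone labels (`"A"`, `"B"`, `"ignorance"`,
#'   `"C"`, `"D"`, `"out-of-range"`).
#' @examples
#' classify_depth_zone(c(5, 100, 300))
#' @export
classify_depth_zone <- function(depth,
                                bounds = c(a_b = 10, b_ign = 40, ign_c = 200,
                                           c_d = 500, max = 1000)) {
  stopifnot(all(depth >= 0))
  out <- character(length(depth))
  out[depth < bounds["a_b"]] <- "A"
  out[depth >= bounds["a_b"] & depth < bounds["b_ign"]] <- "B"
  out[depth >= bounds["b_ign"] & depth < bounds["ign_c"]] <- "ignorance"
  out[depth >= bounds["ign_c"] & depth < bounds["c_d"]] <- "C"
  out[depth >= bounds["c_d"] & depth <= bounds["max"]] <- "D"
  out[depth > bounds["max"]] <- "out-of-range"
  out
}

#' Per-zone correlation of sea-ice duration and blue carbon
#'
#' Runs [pearson()] on `(seaice_duration, blue_carbon)` within each depth
#' zone and classifies the sign: `positive` / `negative` when `p < alpha`,
#' `none` when not significant, `insufficient` for the ignorance zone, zones
#' with fewer than `min_n` samples, or undefined correlations. No
#' multiple-testing correction is applied across zones (noted in the output
#' attribute `metadata`).
#'
#' @param samples Data frame with columns `depth`, `seaice_duration`,
#'   `blue_carbon` (see [gen_benthic_samples()] / [read_benthic_csv()]).
#' @param alpha Two-sided significance level (default 0.05).
#' @param min_n Minimum per-zone sample size (default 3).
#' @param bounds Zone breakpoints, passed to [classify_depth_zone()].
#' @return Data frame of class `zone_result`: `zone`, `depth_min`,
#'   `depth_max`, `n`, `r`, `p`, `sign_class`.
#' @export
zone_correlations <- function(samples, alpha = 0.05, min_n = 3,
                              bounds = c(a_b = 10, b_ign = 40, ign_c = 200,
                                         c_d = 500, max = 1000)) {
  if (!nrow(samples)) stop("no samples supplied", call. = FALSE)
  stopifnot(all(c("depth", "seaice_duration", "blue_carbon") %in% names(samples)))
  zones <- data.frame(
    zone = c("A", "B", "ignorance", "C", "D"),
    depth_min = c(0, bounds[["a_b"]], bounds[["b_ign"]], bounds[["ign_c"]],
                  bounds[["c_d"]]),
    depth_max = c(bounds[["a_b"]], bounds[["b_ign"]], bounds[["ign_c"]],
                  bounds[["c_d"]], bounds[["max"]]),
    stringsAsFactors = FALSE
  )
  lab <- classify_depth_zone(samples$depth, bounds)
  res <- lapply(seq_len(nrow(zones)), function(i) {
    z <- zones$zone[i]
    sub <- samples[lab == z, , drop = FALSE]
    row <- data.frame(zone = z, depth_min = zones$depth_min[i],
                      depth_max = zones$depth_max[i], n = nrow(sub),
                      r = NA_real_, p = NA_real_,
                      sign_class = "insufficient", stringsAsFactors = FALSE)
    if (z == "ignorance" || nrow(sub) < min_n) return(row)
    pr <- pearson(sub$seaice_duration, sub$blue_carbon)
    if (!pr$defined) return(row)
    row$r <- pr$r; row$p <- pr$p
    row$sign_class <- if (pr$p < alpha) {
      if (pr$r > 0) "positive" else "negative"
    } else "none"
    row
  })
  out <- do.call(rbind, res)
  attr(out, "metadata") <- list(alpha = alpha, min_n = min_n,
                                multiple_testing = "none (per-zone tests are reported unadjusted)")
  class(out) <- c("zone_result", "data.frame")
  out
}

#' Fit the fast-ice duration versus scour-frequency relationship
#'
#' Pearson correlation plus ordinary least-squares slope of the annual
#' proportion of monitored shallow seabed struck by icebergs on fast-ice
#' duration. The published shallow monitoring record shows a strong
#' negative relationship (r about -0.86): less fast ice means less
#' obstruction to wind-driven iceberg travel, hence more scour.
#'
#' @param series Data frame with columns `fastice_duration` (days) and
#'   `scoured_proportion` (fraction in `[0, 1]`), one row per year.
#' @return List: `r`, `p`, `slope` (proportion per ice day), `n`,
#'   `defined`.
#' @export
fastice_scour_fit <- function(series) {
  stopifnot(all(c("fastice_duration", "scoured_proportion") %in% names(series)))
  if (nrow(series) < 3) stop("need at least 3 years of monitoring", call. = FALSE)
  pr <- pearson(series$fastice_duration, series$scoured_proportion)
  slope <- if (pr$defined) {
    unname(stats::coef(stats::lm(scoured_proportion ~ fastice_duration,
                                 data = series))[2])
  } else NA_real_
  c(pr[c("r", "p")], list(slope = slope, n = pr$n, defined = pr$defined))
}
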