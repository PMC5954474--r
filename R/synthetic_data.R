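#' @title Seeded synthetic-data generators
#'
#' @description
#' Generators that emulate the statistical structure the analyses assume,
#' so every pipeline stage is testable without external data: an annual
#' shallow-water monitoring series with a strong negative fast-ice/scour
#' relationship, depth-zoned benthic samples whose sea-ice/blue-carbon
#' correlation signs are (+, 0, -, 0) across zones A/B/C/D by default, and
#' a giant-iceberg census registry honouring hard count constraints
#' (total, number above 1000 km2, number grounded, a majority in the
#' 100-500 km2 band). All generators are exactly reproducible from their
#' seed.
#'
#' @name synthetic_data
NULL

#' Generate an annual fast-ice / scour monitoring series
#'
#' `scoured_proportion = clip(a - b * fastice_duration + noise, 0, 1)`.
#' Defaults: intercept `a = 0.9` and slope `b` calibrated so that 300
#' fast-ice days give about 5% of the monitored seabed scoured; Gaussian
#' noise sd 0.1; fast-ice duration drawn uniformly on 30-310 days (within
#' which the noiseless rule never clips).
#'
#' @param n_years Number of monitored years (>= 1). 14 approximates the
#'   length of the longest shallow scour-monitoring record (2003 onward).
#' @param seed Integer seed.
#' @param intercept Scoured proportion extrapolated to zero fast ice.
#' @param slope Decline in scoured proportion per fast-ice day.
#' @param noise_sd Gaussian noise standard deviation.
#' @param fastice_range Uniform sampling range for fast-ice duration (days).
#' @param station Station label.
#' @return Data frame: `year`, `fastice_duration`, `scoured_proportion`,
#'   `station`, `depth_band`.
#' @export
gen_monitoring_series <- function(n_years = 14, seed = 1L,
                                  intercept = 0.9,
                                  slope = (0.9 - 0.05) / 300,
                                  noise_sd = 0.1,
                                  fastice_range = c(30, 310),
                                  station = "synthetic-1") {
  stopifnot(n_years >= 1, noise_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ice <- stats::runif(n_years, fastice_range[1], fastice_range[2])
  prop <- intercept - slope * ice + stats::rnorm(n_years, 0, noise_sd)
  data.frame(year = seq_len(n_years),
             fastice_duration = ice,
             scoured_proportion = pmin(1, pmax(0, prop)),
             station = station,
             depth_band = "5-25 m",
             stringsAsFactors = FALSE)
}

#' Generate depth-zoned benthic samples
#'
#' Per zone: depths uniform within the band, sea-ice duration uniform on
#' 50-300 days, and
#' `blue_carbon = baseline(depth) + zone_slope * seaice_duration + noise`,
#' floored at zero. Default zone slopes (+0.02, 0, -0.02, 0) t C km-2 per
#' ice day for (A, B, C, D) reproduce the observed sign structure; the
#' ignorance zone (40-200 m) gets no samples, emulating the real sampling
#' gap. The baseline declines gently with depth (15 - 0.01 * depth).
#'
#' @param n_per_zone Samples per sampled zone (>= 0).
#' @param seed Integer seed.
#' @param slopes Named numeric: blue-carbon slope on sea-ice duration for
#'   zones A, B, C, D.
#' @param noise_sd Gaussian noise sd (t C km-2), default 0.5.
#' @param seaice_range Uniform range for sea-ice duration (days yr-1).
#' @return Data frame: `depth`, `seaice_duration`, `blue_carbon`, `site`.
#' @export
gen_benthic_samples <- function(n_per_zone = 50, seed = 1L,
                                slopes = c(A = 0.02, B = 0, C = -0.02, D = 0),
                                noise_sd = 0.5,
                                seaice_range = c(50, 300)) {
  stopifnot(n_per_zone >= 0, noise_sd >= 0)
  if (n_per_zone == 0) {
    return(data.frame(depth = numeric(0), seaice_duration = numeric(0),
                      blue_carbon = numeric(0), site = character(0),
                      stringsAsFactors = FALSE))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  bands <- list(A = c(0, 10), B = c(10, 40), C = c(200, 500), D = c(500, 1000))
  out <- lapply(names(bands), function(z) {
    depth <- stats::runif(n_per_zone, bands[[z]][1], bands[[z]][2])
    ice <- stats::runif(n_per_zone, seaice_range[1], seaice_range[2])
    bc <- (15 - 0.01 * depth) + slopes[[z]] * ice +
      stats::rnorm(n_per_zone, 0, noise_sd)
    data.frame(depth = depth, seaice_duration = ice,
               blue_carbon = pmax(0, bc),
               site = paste0("syn-", z, "-", seq_len(n_per_zone)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a synthetic giant-iceberg census registry
#'
#' Produces exactly `total` records of which exactly `n_large` exceed
#' 1000 km2 and exactly `n_grounded` are grounded, with at least half of
#' all areas in the 100-500 km2 band (giant-iceberg size distributions are
#' heavy-tailed; areas are drawn log-uniformly within each band). All
#' areas exceed the 30 km2 giant-iceberg threshold. The default census is
#' the March 2017 one: 47 giants, 6 above 1000 km2, 4 grounded.
#'
#' @param total Total number of giant icebergs.
#' @param n_large Number with area > 1000 km2 (<= total).
#' @param n_grounded Number grounded (<= total).
#' @param seed Integer seed.
#' @param mid_band_share Fraction of the census placed in the 100-500 km2
#'   band (deterministic count `round(share * total)`, default 0.6).
#' @return Data frame: `id`, `area_km2`, `status` (one of `fasted`,
#'   `grounded`, `roaming-shelf`, `roaming-deep`), `region`.
#' @export
gen_iceberg_registry <- function(total = 47, n_large = 6, n_grounded = 4,
                                 seed = 1L, mid_band_share = 0.6) {
  stopifnot(total >= 0)
  if (n_large > total || n_grounded > total || n_large < 0 || n_grounded < 0) {
    stop("inconsistent census counts: need 0 <= n_large, n_grounded <= total",
         call. = FALSE)
  }
  if (total == 0) {
    return(data.frame(id = character(0), area_km2 = numeric(0),
                      status = character(0), region = character(0),
                      stringsAsFactors = FALSE))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  n_mid <- min(total - n_large, round(mid_band_share * total))
  n_rest <- total - n_large - n_mid
  n_small <- ceiling(n_rest / 2)   # 30-100 km2
  n_big <- n_rest - n_small        # 500-1000 km2

  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  areas <- c(runif_log(n_large, 1000, 3500),
             runif_log(n_mid, 100, 500),
             runif_log(n_small, 31, 100),
             runif_log(n_big, 500, 1000))

  statuses <- c(rep("grounded", n_grounded),
                sample(c("fasted", "roaming-shelf", "roaming-deep"),
                       total - n_grounded, replace = TRUE))
  regions <- sample(c("Weddell", "Ross", "Amundsen", "Bellingshausen",
                      "Lazarev", "Cosmonauts", "Davis"), total, replace = TRUE)
  ord <- sample.int(total)
  data.frame(id = sprintf("SYN%02d", seq_len(total)),
             area_km2 = areas[ord],
             status = statuses[ord],
             region = regions,
             stringsAsFactors = FALSE)
}
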