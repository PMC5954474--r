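#' @title Parameter registry for the iceberg blue-carbon models
#'
#' @description
#' Every numeric constant used by the budget, scaling, Monte-Carlo and
#' simulator modules lives here: a point value, a published or assumed
#' low/high range, units, and a short provenance anchor. Downstream code
#' resolves parameters through this registry only, so a user override in a
#' config file propagates everywhere.
#'
#' @name param_registry
NULL

# Registry defaults. low == high == point where no range is published.
# Anchors are short provenance notes in field vocabulary; cite() returns
# them verbatim.
.param_defaults <- function() {
  p <- function(name, point, low, high, units, anchor) {
    data.frame(name = name, point = point, low = low, high = high,
               units = units, anchor = anchor, stringsAsFactors = FALSE)
  }
  rbind(
    p("g0", 7e4, 7e4, 7e4, "t C yr-1 per 5000 km2 iceberg",
      "new open shelf water left by a 5000 km2 calving could generate 7 x 10^4 tonnes of immobilized C per year"),
    p("g", 2.5, 2, 3, "dimensionless",
      "post-collapse benthic growth: two- to threefold increases in sponge density and biomass"),
    p("f", 5, 5, 10, "dimensionless",
      "giant-iceberg fertilization of phytoplankton blooms: x5-10"),
    p("s_seaice", 2, 2, 2, "dimensionless",
      "x2 production increase attributable to regional sea-ice losses"),
    p("q_scour", 0.25, 0.25, 0.25, "fraction",
      "up to a quarter of the area of each grounded iceberg scours"),
    p("a_grounded", 1e4, 1e4, 1e4, "km2",
      "total estimated area of grounded giant icebergs: 10 000 km2"),
    p("groundings_per_year", 8, 8, 8, "yr-1",
      "circumpolar tracking estimate: eight giant icebergs ground per year"),
    p("rho", 16, 8, 16, "t C km-2",
      "benthos near grounded giants holds 8-16 tonnes of standing stock of carbon per square kilometre; climax scour recycles the 16 t maximum"),
    p("p_shallow", 13, 13, 13, "g C m-2 yr-1",
      "zoobenthic production in the shallows: approximately 13 g C m-2 yr-1"),
    p("p_mid", 5, 5, 5, "g C m-2 yr-1",
      "zoobenthic production at 100-300 m: approximately 5 g C m-2 yr-1"),
    p("p_deep", 1.5, 1.5, 1.5, "g C m-2 yr-1",
      "zoobenthic production below 300 m: approximately 1.5 g C m-2 yr-1"),
    p("p_o", 3, 3, 3, "g C m-2 yr-1",
      "approximate mean organic carbon production of 3 g C m-2 yr-1 used for the circumpolar ladder"),
    p("c_carbonate", 0.12, 0.12, 0.12, "fraction",
      "carbonate production matches organic production, of which only 12% is carbon"),
    p("shallow_factor", 2, 2, 2, "dimensionless",
      "production in the upper 100 m estimated as equalling the shelf total below it"),
    p("a_shelf", 4.4e6, 4.4e6, 4.4e6, "km2",
      "area of Antarctica's continental shelf: 4.4 x 10^6 km2"),
    p("i_shelf_loss", 10, 10, 10, "Mt C yr-1",
      "new benthic production from ice-shelf losses: as much as 10 Mt C yr-1"),
    p("g_new", 2, 2, 3, "dimensionless",
      "newly ice-shelf-free areas are two to three times more productive than first thought"),
    p("subant_factor", 2, 2, 2, "dimensionless",
      "doubling for sub-Antarctic continental shelf of comparable extent"),
    p("t_rec", 5, 4, 6, "yr",
      "shallow-water blue-carbon standing-stock recovery took 4-6 years"),
    p("wap_shallow_recycle", 8e4, 8e4, 8e4, "t C yr-1",
      "coastal scour across the WAP shallows recycles an estimated 8 x 10^4 tonnes of carbon per year"),
    p("census_total", 47, 47, 47, "count",
      "March 2017 census: 47 giant icebergs larger than 30 km2"),
    p("census_large", 6, 6, 6, "count",
      "March 2017 census: six giants exceeded 1000 km2"),
    p("census_grounded", 4, 4, 4, "count",
      "early 2017: four giant icebergs (8.5%) were grounded and scouring"),
    p("ref_area_km2", 5000, 5000, 5000, "km2",
      "reference giant-iceberg area for the generation chain: 5000 km2")
  )
}

#' Load the model parameter set, with optional overrides
#'
#' Loads the registry defaults and applies user overrides from a named list
#' or a YAML/JSON config file. An override may be a single number (replacing
#' the point value) or a `{point, low, high}` triple. In `strict` mode an
#' override falling outside the default `[low, high]` range is an error; in
#' lenient mode it is accepted, the range is widened to contain it, and the
#' parameter is flagged in `provenance`.
#'
#' @param config `NULL`, a named list of overrides, or the path to a YAML or
#'   JSON file containing one.
#' @param strict Logical; reject out-of-range overrides?
#' @return An object of class `berg_params`: a data frame with columns
#'   `name`, `point`, `low`, `high`, `units`, `anchor`, `provenance`.
#' @examples
#' ps <- load_params()
#' param_point(ps, "g0")
#' ps2 <- load_params(list(f = 10), strict = TRUE)
#' @export
load_params <- function(config = NULL, strict = FALSE) {
  df <- .param_defaults()
  df$provenance <- "default"
  stopifnot(!anyDuplicated(df$name))

  ov <- .read_config(config)
  for (key in names(ov)) {
    i <- match(key, df$name)
    if (is.na(i)) {
      stop("unknown parameter name in config: '", key, "'", call. = FALSE)
    }
    val <- ov[[key]]
    if (is.list(val)) {
      need <- c("point", "low", "high")
      if (!all(need %in% names(val))) {
        stop("override for '", key,
             "' must be a number or a {point, low, high} triple", call. = FALSE)
      }
      trip <- vapply(val[need], .as_number, numeric(1), key = key)
      if (trip["low"] > trip["point"] || trip["point"] > trip["high"]) {
        stop("override for '", key, "' violates low <= point <= high",
             call. = FALSE)
      }
      out_of_range <- trip["low"] < df$low[i] || trip["high"] > df$high[i]
      if (strict && out_of_range) {
        stop("override for '", key, "' outside default range [",
             df$low[i], ", ", df$high[i], "]", call. = FALSE)
      }
      df$point[i] <- trip["point"]
      df$low[i] <- trip["low"]
      df$high[i] <- trip["high"]
      df$provenance[i] <- if (out_of_range) "overridden (out of range)" else "overridden"
    } else {
      x <- .as_number(val, key)
      out_of_range <- x < df$low[i] || x > df$high[i]
      if (strict && out_of_range) {
        stop("override for '", key, "' = ", x, " outside default range [",
             df$low[i], ", ", df$high[i], "]", call. = FALSE)
      }
      df$point[i] <- x
      df$low[i] <- min(df$low[i], x)
      df$high[i] <- max(df$high[i], x)
      df$provenance[i] <- if (out_of_range) "overridden (out of range)" else "overridden"
    }
  }
  stopifnot(all(df$low <= df$point), all(df$point <= df$high),
            all(nzchar(df$units)), all(nzchar(df$anchor)))
  class(df) <- c("berg_params", "data.frame")
  df
}

.as_number <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("non-numeric value for parameter '", key, "'", call. = FALSE)
  }
  as.numeric(x)
}

.read_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = FALSE))
    }
    return(yaml::read_yaml(config))
  }
  if (!is.list(config)) stop("config must be NULL, a file path or a named list")
  config
}

#' Fetch the point value of a registry parameter
#'
#' @param params A `berg_params` object from [load_params()].
#' @param name Parameter identifier.
#' @return The numeric point value.
#' @export
param_point <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: '", name, "'", call. = FALSE)
  params$point[i]
}

#' Fetch the `[low, high]` range of a registry parameter
#'
#' @inheritParams param_point
#' @return Numeric vector `c(low, high)`.
#' @export
param_range <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: '", name, "'", call. = FALSE)
  c(low = params$low[i], high = params$high[i])
}

#' Return the provenance anchor for a parameter
#'
#' @inheritParams param_point
#' @return The stored anchor string, verbatim.
#' @examples
#' cite(load_params(), "rho")
#' @export
cite <- function(params, name) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: '", name, "'", call. = FALSE)
  params$anchor[i]
}

#' Serialize a parameter set to YAML
#'
#' Writes every parameter as a `{point, low, high}` triple so that reading
#' the file back through [load_params()] reproduces the set exactly.
#'
#' @param params A `berg_params` object.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "berg_params"))
  lst <- lapply(seq_len(nrow(params)), function(i) {
    list(point = params$point[i], low = params$low[i], high = params$high[i])
  })
  names(lst) <- params$name
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @export
print.berg_params <- function(x, ...) {
  cat("Blue-carbon model parameters (", nrow(x), " entries)\n", sep = "")
  print.data.frame(x[, c("name", "point", "low", "high", "units", "provenance")],
                   row.names = FALSE, ...)
  invisible(x)
}
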