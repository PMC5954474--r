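#' @title Circumpolar zoobenthic production scaling ladder
#'
#' @description
#' Scales a per-area zoobenthic carbon production rate up to a circumpolar
#' total: organic + carbonate carbon per km2, doubling for the little-sampled
#' shallows, multiplying by the continental-shelf area, then the sea-ice-loss,
#' ice-shelf-loss and sub-Antarctic rungs. Reported (rounded) values propagate
#' rung to rung, matching the published 30 -> 60 -> 80 -> 160 Mt chain; the
#' raw branch is carried alongside.
#'
#' @name circumpolar_scaling
NULL

#' Per-area zoobenthic carbon production rate
#'
#' `p_o * (1 + c)`: mean organic production plus an equal mass of carbonate
#' production of which only the fraction `c` is carbon. Uses the exact unit
#' identity 1 g C m-2 yr-1 = 1 t C km-2 yr-1.
#'
#' @param p_o Mean organic carbon production (g C m-2 yr-1).
#' @param c_frac Carbon fraction of carbonate production, in `[0, 1]`.
#' @return List with `raw` and `reported` (nearest two significant figures),
#'   in t C km-2 yr-1.
#' @examples
#' areal_rate(3, 0.12)$reported # 3.4
#' @export
areal_rate <- function(p_o, c_frac) {
  stopifnot(p_o >= 0, c_frac >= 0, c_frac <= 1)
  raw <- p_o * (1 + c_frac)
  list(raw = raw, reported = report_round(raw, "nearest-2sf"))
}

#' Add the shallow (< 100 m) contribution
#'
#' The upper 100 m is little sampled but has been estimated to equal the
#' whole shelf production below it, hence a default doubling.
#'
#' @param rate Shelf rate below 100 m (t C km-2 yr-1).
#' @param factor Multiplier for including the shallows (default 2).
#' @return `rate * factor`.
#' @export
include_shallows <- function(rate, factor = 2) {
  stopifnot(rate >= 0, factor >= 0)
  rate * factor
}

#' Continental-shelf total production
#'
#' @param rate Per-area rate (t C km-2 yr-1).
#' @param area Shelf area (km2).
#' @return List with `raw` and `reported` (nearest two significant figures),
#'   in Mt C yr-1.
#' @examples
#' shelf_total(6.8, 4.4e6)$reported # 30
#' @export
shelf_total <- function(rate, area) {
  stopifnot(rate >= 0, area >= 0)
  raw <- rate * area / 1e6
  list(raw = raw, reported = report_round(raw, "nearest-2sf"))
}

#' Scenario ladder from the shelf total to the circumpolar estimate
#'
#' Three rungs on top of the base shelf total: (1) multiply by the
#' sea-ice-loss production increase `s`; (2) add ice-shelf-loss production
#' `I` scaled by the new-area growth factor; (3) multiply by the
#' sub-Antarctic factor.
#'
#' @param base Base shelf total (Mt C yr-1).
#' @param s Sea-ice-loss multiplier.
#' @param I_mt New production from ice-shelf losses (Mt C yr-1).
#' @param g_new Growth factor for newly ice-shelf-free areas.
#' @param subant Sub-Antarctic shelf multiplier.
#' @return An object of class `scaling_ladder`: a data frame of rungs
#'   `(label, input, operation, result)` plus attribute `final_total`.
#' @examples
#' scenario_ladder(30, 2, 10, 2, 2) # rungs 60, 80, 160
#' @export
scenario_ladder <- function(base, s, I_mt, g_new, subant) {
  stopifnot(base >= 0, s >= 0, I_mt >= 0, g_new >= 0, subant >= 0)
  r1 <- base * s
  r2 <- r1 + I_mt * g_new
  r3 <- r2 * subant
  rungs <- data.frame(
    label = c("sea-ice losses", "ice-shelf losses", "sub-Antarctic shelves"),
    input = c(base, r1, r2),
    operation = c(sprintf("x %g", s),
                  sprintf("+ %g x %g", I_mt, g_new),
                  sprintf("x %g", subant)),
    result = c(r1, r2, r3),
    stringsAsFactors = FALSE
  )
  structure(rungs, final_total = r3, class = c("scaling_ladder", "data.frame"))
}

#' Replay a scaling ladder from its recorded rungs
#'
#' Re-applies each rung's operation to its recorded input and checks the
#' chain is internally consistent (each rung's input is the previous rung's
#' result).
#'
#' @param ladder A `scaling_ladder`.
#' @return The recomputed final total (equal to `attr(ladder, "final_total")`
#'   for a consistent ladder).
#' @export
replay_ladder <- function(ladder) {
  stopifnot(inherits(ladder, "scaling_ladder"))
  val <- ladder$input[1]
  for (i in seq_len(nrow(ladder))) {
    if (ladder$input[i] != val) stop("ladder rungs are not chained", call. = FALSE)
    op <- ladder$operation[i]
    val <- if (startsWith(op, "x ")) {
      val * as.numeric(sub("^x ", "", op))
    } else {
      parts <- as.numeric(strsplit(sub("^\\+ ", "", op), " x ")[[1]])
      val + parts[1] * parts[2]
    }
    if (!isTRUE(all.equal(val, ladder$result[i]))) {
      stop("ladder rung ", i, " does not replay", call. = FALSE)
    }
  }
  val
}

#' Percentage of giant icebergs grounded
#'
#' @param n_grounded Number grounded.
#' @param n_total Census total (> 0).
#' @return Percentage, rounded to one decimal place.
#' @examples
#' grounded_fraction(4, 47) # 8.5
#' @export
grounded_fraction <- function(n_grounded, n_total) {
  if (n_total <= 0) stop("census total must be positive", call. = FALSE)
  stopifnot(n_grounded >= 0, n_grounded <= n_total)
  round(100 * n_grounded / n_total, 1)
}

#' Run the full circumpolar scaling ladder from registry parameters
#'
#' Convenience wrapper chaining [areal_rate()], [include_shallows()],
#' [shelf_total()] and [scenario_ladder()], propagating reported values
#' rung-to-rung (raw branch returned alongside).
#'
#' @param params A `berg_params` registry.
#' @return List with `rate` (areal), `rate_with_shallows`, `shelf_mt`
#'   (each raw + reported), and `ladder` (a `scaling_ladder` on the reported
#'   branch) plus `ladder_raw` (unrounded branch).
#' @export
circumpolar_estimate <- function(params = load_params()) {
  ar <- areal_rate(param_point(params, "p_o"), param_point(params, "c_carbonate"))
  sf <- param_point(params, "shallow_factor")
  ws <- list(raw = include_shallows(ar$raw, sf),
             reported = include_shallows(ar$reported, sf))
  st <- shelf_total(ws$reported, param_point(params, "a_shelf"))
  st_raw <- shelf_total(ws$raw, param_point(params, "a_shelf"))
  args <- list(s = param_point(params, "s_seaice"),
               I_mt = param_point(params, "i_shelf_loss"),
               g_new = param_point(params, "g_new"),
               subant = param_point(params, "subant_factor"))
  list(
    rate = ar,
    rate_with_shallows = ws,
    shelf_mt = list(raw = st_raw$raw, reported = st$reported),
    ladder = do.call(scenario_ladder, c(list(base = st$reported), args)),
    ladder_raw = do.call(scenario_ladder, c(list(base = st_raw$raw), args))
  )
}
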