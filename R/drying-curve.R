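#' Drying experiment design
#'
#' Describes the sampling design of the solar-drying experiment: one batch of
#' boiled shrimp sampled at `stage_times` hours of drying, with
#' `replicates_per_stage` shrimp per stage. The default (boiled = 0 h, then
#' 1..12 h, 8 replicates) yields the 104-sample layout of the study the
#' package emulates.
#'
#' @param stage_times Strictly increasing drying times in hours; time 0 is
#'   the boiled (undried) stage.
#' @param replicates_per_stage Number of shrimp sampled per stage (>= 1).
#' @param seed Integer seed controlling all randomness downstream.
#' @return A list of class `drying_design`.
#' @export
#' @examples
#' d <- drying_design()
#' length(d$stage_times) * d$replicates_per_stage  # 104
drying_design <- function(stage_times = 0:12, replicates_per_stage = 8L,
                          seed = 1L) {
  stage_times <- as.numeric(stage_times)
  if (any(diff(stage_times) <= 0)) {
    abort("`stage_times` must be strictly increasing")
  }
  replicates_per_stage <- as.integer(replicates_per_stage)
  if (replicates_per_stage < 1L) abort("`replicates_per_stage` must be >= 1")
  structure(
    list(stage_times = stage_times,
         replicates_per_stage = replicates_per_stage,
         seed = as.integer(seed)),
    class = "drying_design"
  )
}

#' Drying-curve parameters
#'
#' Parameterizes the moisture-content (MC) trajectory of shrimp during solar
#' drying as a normalized logistic decay: slow loss in the first ~2 h, a
#' maximum drying rate at `t_mid` (4 h, ~8.3 percentage points of MC per
#' hour under the defaults), and slow loss again after ~7 h. The curve is
#' pinned exactly to `mc_start` at t = 0 and `mc_end` at `t_final`, the
#' anchors reported for boiled (72.75 % wet basis) and fully dried
#' (15.67 %) shrimp.
#'
#' @param mc_start MC mass fraction at t = 0 (boiled).
#' @param mc_end MC mass fraction at `t_final`.
#' @param t_mid Hour of maximum drying rate.
#' @param t_scale Logistic time scale (h); controls how sharply the fast
#'   drying phase is concentrated around `t_mid`.
#' @param t_final Final design time (h) at which the curve equals `mc_end`.
#' @param replicate_sd Between-replicate MC standard deviation (mass
#'   fraction) used by the dataset generator.
#' @return A list of class `drying_curve_params`.
#' @export
drying_curve_params <- function(mc_start = 0.7275, mc_end = 0.1567,
                                t_mid = 4, t_scale = 2, t_final = 12,
                                replicate_sd = 0.015) {
  if (!(mc_end > 0 && mc_start > mc_end && mc_start < 1)) {
    abort("need 0 < mc_end < mc_start < 1")
  }
  if (t_scale <= 0 || t_final <= 0) abort("t_scale and t_final must be positive")
  structure(
    list(mc_start = mc_start, mc_end = mc_end, t_mid = t_mid,
         t_scale = t_scale, t_final = t_final, replicate_sd = replicate_sd),
    class = "drying_curve_params"
  )
}

#' Ground-truth drying curve
#'
#' Deterministic expected moisture content (mass fraction) after `t` hours
#' of drying. A logistic survival term is rescaled so that the curve passes
#' exactly through `mc_start` at t = 0 and `mc_end` at `t_final`; it is
#' continuous and nonincreasing for all t >= 0 (beyond `t_final` it decays
#' asymptotically slightly below `mc_end`).
#'
#' @param t Drying time in hours (vectorized, must be >= 0).
#' @param params A [drying_curve_params()] object.
#' @return Moisture content as a mass fraction, same length as `t`.
#' @export
#' @examples
#' mc_curve(c(0, 12)) * 100  # 72.75, 15.67
mc_curve <- function(t, params = drying_curve_params()) {
  t <- as.numeric(t)
  if (any(t < 0)) abort("drying time `t` must be nonnegative")
  s <- function(x) stats::plogis(-(x - params$t_mid) / params$t_scale)
  s0 <- s(0)
  sT <- s(params$t_final)
  params$mc_end + (params$mc_start - params$mc_end) * (s(t) - sT) / (s0 - sT)
}

#' Moisture content from oven-drying weights
#'
#' Gravimetric reference MC: a sample is weighed in a dried bottle before
#' (`m2`) and after (`m3`) oven drying; `m1` is the empty bottle. MC is the
#' lost water mass over the wet sample mass, `(m2 - m3) / (m2 - m1)`,
#' returned as a mass fraction in `[0, 1]` (multiply by 100 to present as
#' g/100 g).
#'
#' @param m1 Bottle weight (g).
#' @param m2 Bottle + wet sample weight (g); must exceed `m1`.
#' @param m3 Bottle + dried sample weight (g); must not exceed `m2`.
#' @return Moisture mass fraction, vectorized over the inputs.
#' @export
#' @examples
#' compute_mc(10, 20, 15)  # 0.5
compute_mc <- function(m1, m2, m3) {
  if (any(m2 <= m1)) abort("degenerate sample mass: need m2 > m1")
  if (any(m3 > m2)) abort("negative drying loss: need m3 <= m2")
  (m2 - m3) / (m2 - m1)
}
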