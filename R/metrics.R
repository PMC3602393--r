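# Illness and wellness metrics.
#
# Both scores summarise a triplet of on-drive band powers (20, 30, 40 Hz)
# against a reference triplet. The illness metric rewards the
# schizophrenia-like pattern: unchanged 20 / 30 Hz responses with a
# selective ~26 % reduction of the 40 Hz response (the clinically
# calibrated target). The wellness metric rewards a treated model for
# returning exactly to control behaviour.

#' Metric configuration
#'
#' @param target_decrease fractional 40 Hz decrease scoring 1 on the
#'   illness metric (default 0.26).
#' @param illness_tolerance allowed fractional 20 / 30 Hz deviation before
#'   an illness score of 0 (default 0.075).
#' @param wellness_tolerance the same for the wellness metric (default
#'   0.10).
#' @param falloff linear falloff scale: the illness score reaches 0 when
#'   the 40 Hz decrease differs from the target by `falloff` (default
#'   0.26, so the score is 0 at decreases of 0 % and 52 %); the wellness
#'   score reaches 0 at a relative 40 Hz deviation of `falloff`.
#' @param params parameter list supplying defaults.
#' @return object of class `hg_metric_config`.
#' @export
metric_config <- function(target_decrease = NULL, illness_tolerance = NULL,
                          wellness_tolerance = NULL, falloff = NULL,
                          params = default_params()) {
  m <- params$metrics
  cfg <- list(target_decrease = target_decrease %||% m$target_decrease,
              illness_tolerance = illness_tolerance %||% m$illness_tolerance,
              wellness_tolerance = wellness_tolerance %||% m$wellness_tolerance,
              falloff = falloff %||% m$falloff)
  abort_if(cfg$target_decrease <= 0 || cfg$target_decrease >= 1,
           "target_decrease must be in (0, 1)")
  abort_if(cfg$illness_tolerance <= 0 || cfg$wellness_tolerance <= 0 ||
             cfg$falloff <= 0, "tolerances and falloff must be positive")
  structure(cfg, class = "hg_metric_config")
}

check_powers <- function(x, what) {
  x <- unlist(x)
  abort_if(length(x) < 3, "%s must supply band powers at 20, 30 and 40 Hz",
           what)
  if (is.null(names(x)) || !all(c("20", "30", "40") %in% names(x))) {
    names(x) <- as.character(c(20, 30, 40))
  }
  x[c("20", "30", "40")]
}

#' Illness metric: schizophrenia-likeness of a model run
#'
#' Returns 0 if either the 20 or the 30 Hz response deviates from baseline
#' by more than the tolerance. Otherwise the fractional 40 Hz decrease
#' `d = (base40 - test40) / base40` is scored
#' `max(0, 1 - |d - target| / falloff)`: exactly the target decrease (26 %)
#' scores 1; the score falls off linearly and symmetrically in `|d - 26 %|`.
#'
#' @param base baseline (control) band powers, named `"20"`, `"30"`,
#'   `"40"` (a [band_powers()] result).
#' @param test band powers of the tested condition.
#' @param cfg an [metric_config()].
#' @return score in `[0, 1]`.
#' @export
illness_metric <- function(base, test, cfg = metric_config()) {
  base <- check_powers(base, "base"); test <- check_powers(test, "test")
  abort_if(any(base <= 0), "baseline band powers must be positive")
  if (abs(test[["20"]] / base[["20"]] - 1) > cfg$illness_tolerance ||
      abs(test[["30"]] / base[["30"]] - 1) > cfg$illness_tolerance) {
    return(0)
  }
  d <- (base[["40"]] - test[["40"]]) / base[["40"]]
  err <- abs(d - cfg$target_decrease)
  if (err < 1e-9) err <- 0 # numerical guard: exact target scores exactly 1
  max(0, 1 - err / cfg$falloff)
}

#' Wellness metric: drug-induced return to control behaviour
#'
#' Returns 0 if the treated 20 or 30 Hz response deviates from control by
#' more than the (10 %) tolerance; otherwise decreases linearly from 1 in
#' the relative 40 Hz deviation `|treated40 - control40| / control40`.
#'
#' @param control control-model band powers.
#' @param treated treated (drugged schizophrenic) band powers.
#' @param cfg an [metric_config()].
#' @return score in `[0, 1]`.
#' @export
wellness_metric <- function(control, treated, cfg = metric_config()) {
  control <- check_powers(control, "control")
  treated <- check_powers(treated, "treated")
  abort_if(any(control <= 0), "control band powers must be positive")
  if (abs(treated[["20"]] / control[["20"]] - 1) > cfg$wellness_tolerance ||
      abs(treated[["30"]] / control[["30"]] - 1) > cfg$wellness_tolerance) {
    return(0)
  }
  dev <- abs(treated[["40"]] - control[["40"]]) / control[["40"]]
  if (dev < 1e-9) dev <- 0
  max(0, 1 - dev / cfg$falloff)
}
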