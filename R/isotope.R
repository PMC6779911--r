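#' 15N labeling rate from a labeled-fraction time series
#'
#' Percentage of a metabolite pool that becomes labeled per hour,
#' calculated from the labeled fraction at the reference timepoint:
#' `rate = 100 * f(t_ref) / t_ref` (percent per hour). For an exponential
#' curve `f(t) = 1 - exp(-k t)` this recovers `100 (1 - exp(-k t_ref)) /
#' t_ref`, which approaches `100 k` for small `k`.
#'
#' @param series data.frame with `time_h` and `labeled_fraction`.
#' @param reference_time Reference timepoint in hours (default 3).
#' @return Labeling rate in percent per hour.
#' @export
labelingRate <- function(series, reference_time = 3) {
  i <- which(series$time_h == reference_time)
  if (!length(i)) stop("reference timepoint absent from series")
  100 * series$labeled_fraction[i[1]] / reference_time
}

#' Metabolite composition percentages
#'
#' Each pool expressed as a percentage of the total over the measured set.
#'
#' @param pools Named nonnegative metabolite amounts (not all zero).
#' @return Named percentages summing to 100.
#' @export
compositionPercent <- function(pools) {
  if (any(pools < 0)) stop("pool sizes must be nonnegative")
  tot <- sum(pools)
  if (tot == 0) stop("all pools are zero")
  100 * pools / tot
}
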