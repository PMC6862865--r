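#' Two-component log-normal ground truth for cytometry events
#'
#' Flow-cytometry intensity distributions (e.g. TMRM membrane-potential or
#' DHE superoxide signals) are modelled as a mixture of a "low" and a "high"
#' log-normal population with mixing proportion `pi_high`.
#'
#' @param n number of events.
#' @param pi_high proportion of events from the high population, in `[0,1]`.
#' @param meanlog_low,sdlog_low,meanlog_high,sdlog_high log-scale location
#'   and scale of the two populations.
#' @return class `cytometry_truth` (a list of the parameters).
#' @export
cytometry_truth <- function(n, pi_high, meanlog_low = log(100),
                            sdlog_low = 0.3, meanlog_high = log(1000),
                            sdlog_high = 0.3) {
  stopifnot(n >= 1, pi_high >= 0, pi_high <= 1,
            sdlog_low > 0, sdlog_high > 0)
  structure(list(n = as.integer(n), pi_high = pi_high,
                 meanlog_low = meanlog_low, sdlog_low = sdlog_low,
                 meanlog_high = meanlog_high, sdlog_high = sdlog_high),
            class = "cytometry_truth")
}

#' One cytometry sample: per-event intensities
#'
#' @param intensity numeric vector of non-negative event intensities.
#' @param label sample label.
#' @return class `event_sample`.
#' @export
event_sample <- function(intensity, label = "sample") {
  intensity <- as.numeric(intensity)
  if (length(intensity) < 1) stop("event_sample: need at least one event")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("event_sample: intensities must be finite and >= 0")
  }
  structure(list(intensity = intensity, label = label,
                 n = length(intensity)),
            class = "event_sample")
}

#' Draw a seeded event sample from a cytometry mixture truth
#'
#' @param truth a [cytometry_truth()].
#' @param seed integer seed.
#' @param label sample label.
#' @return an [event_sample()].
#' @export
generate_cytometry_events <- function(truth, seed = 1L, label = "sample") {
  stopifnot(inherits(truth, "cytometry_truth"))
  set.seed(as.integer(seed))
  high <- stats::runif(truth$n) < truth$pi_high
  x <- numeric(truth$n)
  x[high] <- stats::rlnorm(sum(high), truth$meanlog_high, truth$sdlog_high)
  x[!high] <- stats::rlnorm(sum(!high), truth$meanlog_low, truth$sdlog_low)
  event_sample(x, label)
}

#' Synthetic plate-reader table (signal + nuclei-stain normalization)
#'
#' Emulates e.g. a MitoSOX read followed by a DAPI read on the same wells:
#' per-well cell count varies log-normally, the raw signal is
#' (per-cell signal) x (cell count) with multiplicative noise, and the
#' normalization channel is proportional to cell count.
#'
#' @param group_means named numeric vector: true per-cell signal per group.
#' @param n_wells wells per group.
#' @param cv multiplicative coefficient of variation of the signal.
#' @param cell_count_cv spread of the per-well cell-count factor.
#' @param seed integer seed.
#' @return data.frame with columns `well`, `group`, `signal`, `normalizer`.
#' @export
generate_plate_table <- function(group_means, n_wells = 6, cv = 0.1,
                                 cell_count_cv = 0.2, seed = 1L) {
  stopifnot(!is.null(names(group_means)), all(group_means > 0))
  set.seed(as.integer(seed))
  rows <- lapply(names(group_means), function(g) {
    cells <- exp(stats::rnorm(n_wells, 0, cell_count_cv))
    sig <- group_means[[g]] * cells * exp(stats::rnorm(n_wells, 0, cv))
    data.frame(well = paste0(g, "_", seq_len(n_wells)), group = g,
               signal = sig, normalizer = 1000 * cells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic densitometry table (target band vs loading control)
#'
#' Per lane, the loading-control band intensity varies log-normally (loading
#' differences) and the target band is (true ratio) x (control) with
#' multiplicative noise — the structure of an immunoblot quantified against
#' a loading control such as beta-actin or Alix.
#'
#' @param group_ratios named numeric vector: true target/control ratio per
#'   group.
#' @param n_lanes lanes per group.
#' @param control_mean mean loading-control intensity.
#' @param cv multiplicative noise on the target band.
#' @param loading_cv spread of the control band across lanes.
#' @param target,control band names recorded in the table.
#' @param seed integer seed.
#' @return data.frame with columns `lane`, `group`, `target`, `control`,
#'   `target_intensity`, `control_intensity`.
#' @export
generate_densitometry_table <- function(group_ratios, n_lanes = 3,
                                        control_mean = 1000, cv = 0.05,
                                        loading_cv = 0.15,
                                        target = "alpha-synuclein",
                                        control = "Alix", seed = 1L) {
  stopifnot(!is.null(names(group_ratios)), all(group_ratios >= 0))
  set.seed(as.integer(seed))
  rows <- lapply(names(group_ratios), function(g) {
    ctrl <- control_mean * exp(stats::rnorm(n_lanes, 0, loading_cv))
    tgt <- group_ratios[[g]] * ctrl * exp(stats::rnorm(n_lanes, 0, cv))
    data.frame(lane = paste0(g, "_", seq_len(n_lanes)), group = g,
               target = target, control = control,
               target_intensity = tgt, control_intensity = ctrl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
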