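#' Percent of events above a positive-control threshold
#'
#' Cytometry gating against a biological positive control: the control
#' sample (e.g. FCCP-treated cells whose mitochondrial membrane potential
#' is collapsed) defines the threshold as its `q`-quantile, and the sample
#' readout is the percentage of events strictly above that threshold. The
#' statistic depends only on ranks, so it is invariant under any strictly
#' increasing transform applied to both samples (detector gain, log
#' display).
#'
#' @param sample,control [event_sample()] objects.
#' @param q control quantile defining the gate (default 0.95: 5% of
#'   control events fall above their own threshold).
#' @return percent of sample events above threshold, with the threshold in
#'   attribute `threshold`.
#' @export
percent_above_threshold <- function(sample, control, q = 0.95) {
  stopifnot(inherits(sample, "event_sample"),
            inherits(control, "event_sample"), q > 0, q < 1)
  if (control$n < 100) {
    warning("percent_above_threshold: control has fewer than 100 events; ",
            "the threshold quantile is unstable")
  }
  thr <- stats::quantile(control$intensity, q, names = FALSE)
  pct <- 100 * mean(sample$intensity > thr)
  attr(pct, "threshold") <- thr
  pct
}

#' Location statistics of a cytometry sample
#'
#' Mean, median and geometric mean of the event intensities. The geometric
#' mean is taken over the strictly positive events (no offset is added);
#' the number of zero-intensity events is reported, and an all-zero sample
#' yields a missing geometric mean.
#'
#' @param sample an [event_sample()].
#' @return data.frame: `label`, `n`, `mean`, `median`, `geo_mean`,
#'   `n_zero`.
#' @export
event_statistics <- function(sample) {
  stopifnot(inherits(sample, "event_sample"))
  x <- sample$intensity
  pos <- x[x > 0]
  data.frame(label = sample$label, n = sample$n, mean = mean(x),
             median = stats::median(x),
             geo_mean = if (length(pos)) exp(mean(log(pos))) else NA_real_,
             n_zero = sum(x == 0), stringsAsFactors = FALSE)
}

#' Signal-to-normalizer ratios with group summary
#'
#' The shared readout of plate-reader assays normalized to a nuclei stain
#' (e.g. MitoSOX / DAPI) and of densitometry normalized to a loading
#' control (e.g. phospho-4E-BP1 / beta-actin, or exosomal alpha-synuclein /
#' Alix): per unit (well or lane), ratio = signal / normalizer; per group,
#' mean and SEM of the ratios. Optionally all ratios are rescaled so that a
#' named reference group has mean 1 (fold-change presentation). Ratios are
#' invariant to any common gain applied to both channels.
#'
#' @param table data.frame with a `group` column plus either
#'   `signal`/`normalizer` (plate reader) or
#'   `target_intensity`/`control_intensity` (densitometry) columns.
#' @param reference optional reference group label for rescaling.
#' @return list with `units` (the input table plus a `ratio` column,
#'   rescaled if requested) and `groups` (data.frame: `group`, `n`,
#'   `ratio_mean`, `ratio_sem`).
#' @export
ratio_to_normalizer <- function(table, reference = NULL) {
  stopifnot(is.data.frame(table), "group" %in% names(table))
  if (all(c("signal", "normalizer") %in% names(table))) {
    sig <- table$signal; nrm <- table$normalizer
    unit_col <- if ("well" %in% names(table)) "well" else NULL
  } else if (all(c("target_intensity", "control_intensity") %in% names(table))) {
    sig <- table$target_intensity; nrm <- table$control_intensity
    unit_col <- if ("lane" %in% names(table)) "lane" else NULL
  } else {
    stop("ratio_to_normalizer: need signal/normalizer or ",
         "target_intensity/control_intensity columns")
  }
  if (any(nrm <= 0)) {
    bad <- if (is.null(unit_col)) which(nrm <= 0) else table[[unit_col]][nrm <= 0]
    stop("ratio_to_normalizer: nonpositive normalizer in: ",
         paste(bad, collapse = ", "))
  }
  table$ratio <- sig / nrm
  if (!is.null(reference)) {
    if (!reference %in% table$group) {
      stop("ratio_to_normalizer: reference group '", reference, "' not found")
    }
    table$ratio <- table$ratio / mean(table$ratio[table$group == reference])
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  gs <- split(table$ratio, table$group)
  groups <- data.frame(group = names(gs),
                       n = vapply(gs, length, integer(1)),
                       ratio_mean = vapply(gs, mean, numeric(1)),
                       ratio_sem = vapply(gs, sem, numeric(1)),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(units = table, groups = groups)
}

#' Read cytometry events from CSV
#'
#' Accepts a single-column CSV (one intensity per row, one sample per
#' file) or a long table with `sample` and `intensity` columns.
#'
#' @param path CSV path.
#' @return a single [event_sample()] or a named list of them.
#' @export
read_event_csv <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("sample", "intensity") %in% names(dat))) {
    sp <- split(dat$intensity, dat$sample)
    return(Map(event_sample, sp, names(sp)))
  }
  if (ncol(dat) == 1) {
    return(event_sample(dat[[1]], sub("[.][^.]*$", "", basename(path))))
  }
  stop("read_event_csv: expected one intensity column or sample+intensity")
}
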