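#' Ground-truth parameters for a synthetic extracellular-flux plate
#'
#' Defines the hidden per-well respiration parameters from which
#' [generate_flux_plate()] simulates an OCR/ECAR trace. Scalars are recycled
#' across wells. The derived quantities the analysis layer should recover
#' (coupled respiration, proton leak, spare respiratory capacity, ATP rates)
#' are fully determined by these values.
#'
#' @param basal true basal OCR per well, pmol O2/min (at unit cell scale).
#' @param nonmito true non-mitochondrial OCR (rotenone/antimycin-insensitive),
#'   pmol O2/min. Must not exceed `basal`.
#' @param coupled_frac fraction of mitochondrial basal respiration coupled to
#'   ATP synthesis (oligomycin-sensitive), in `[0, 1]`.
#' @param maximal true maximal (FCCP-uncoupled) OCR, pmol O2/min. Must be at
#'   least `basal` unless `allow_low_maximal = TRUE` (depolarized cells can
#'   fail to respond to uncoupler).
#' @param ecar true extracellular acidification rate, mpH/min.
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise applied per cycle, in OCR units (ECAR noise is scaled by
#'   `ecar/basal`).
#' @param scale dimensionless per-well cell-count scale factor; measured OCR,
#'   ECAR and the nuclei-stain normalization signal are all proportional
#'   to it.
#' @param n_wells number of wells; scalar parameters are recycled.
#' @param allow_low_maximal permit `maximal < basal` (spare respiratory
#'   capacity below 100%).
#' @return An object of class `flux_truth`: a data.frame with one row per
#'   well and columns `well`, `basal`, `nonmito`, `coupled_frac`, `maximal`,
#'   `ecar`, `noise_sd`, `scale`.
#' @examples
#' flux_truth(basal = 100, nonmito = 20, coupled_frac = 0.75, maximal = 180)
#' @export
flux_truth <- function(basal, nonmito, coupled_frac, maximal, ecar = 20,
                       noise_sd = 0, scale = 1, n_wells = NULL,
                       allow_low_maximal = FALSE) {
  n <- if (is.null(n_wells)) {
    max(length(basal), length(nonmito), length(coupled_frac),
        length(maximal), length(ecar), length(noise_sd), length(scale))
  } else {
    n_wells
  }
  tr <- data.frame(
    well         = sprintf("W%02d", seq_len(n)),
    basal        = rep_len(as.numeric(basal), n),
    nonmito      = rep_len(as.numeric(nonmito), n),
    coupled_frac = rep_len(as.numeric(coupled_frac), n),
    maximal      = rep_len(as.numeric(maximal), n),
    ecar         = rep_len(as.numeric(ecar), n),
    noise_sd     = rep_len(as.numeric(noise_sd), n),
    scale        = rep_len(as.numeric(scale), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(tr[-1])))) {
    stop("flux_truth: all parameters must be finite")
  }
  if (any(tr$nonmito > tr$basal)) {
    stop("flux_truth: non-mitochondrial OCR must not exceed basal OCR")
  }
  if (any(tr$coupled_frac < 0 | tr$coupled_frac > 1)) {
    stop("flux_truth: coupled_frac must lie in [0, 1]")
  }
  if (!allow_low_maximal && any(tr$maximal < tr$basal)) {
    stop("flux_truth: maximal OCR below basal; set allow_low_maximal = TRUE ",
         "to simulate uncoupler-unresponsive wells")
  }
  if (any(tr$noise_sd < 0)) stop("flux_truth: noise_sd must be >= 0")
  if (any(tr$scale <= 0)) stop("flux_truth: scale must be > 0")
  class(tr) <- c("flux_truth", "data.frame")
  tr
}

#' Injection schedule for a mito-stress-test run
#'
#' The standard protocol measures basal respiration, then injects oligomycin
#' (blocks ATP synthase), FCCP (uncouples, forcing maximal respiration) and
#' rotenone/antimycin A (shuts down the electron transport chain), in that
#' order. Each measurement cycle is a 30 s mix followed by a 3 min
#' acquisition; the default records four basal cycles and three per
#' injection.
#'
#' @param cycles named integer vector of cycle counts, names exactly
#'   `basal`, `oligo`, `fccp`, `rot_aa` in that order.
#' @param mix_min,measure_min per-cycle mixing and acquisition times
#'   in minutes.
#' @return An object of class `injection_schedule`.
#' @export
injection_schedule <- function(cycles = c(basal = 4L, oligo = 3L,
                                          fccp = 3L, rot_aa = 3L),
                               mix_min = 0.5, measure_min = 3) {
  required <- c("basal", "oligo", "fccp", "rot_aa")
  if (!identical(names(cycles), required)) {
    stop("injection_schedule: phases must be exactly ",
         paste(required, collapse = " -> "), " in that order")
  }
  cycles <- as.integer(cycles)
  names(cycles) <- required
  if (any(is.na(cycles)) || any(cycles < 1L)) {
    stop("injection_schedule: every phase needs a positive cycle count")
  }
  structure(list(cycles = cycles, mix_min = mix_min,
                 measure_min = measure_min),
            class = "injection_schedule")
}

#' Simulate an extracellular-flux plate from ground truth
#'
#' Produces a per-well OCR/ECAR trace whose phase means are, up to additive
#' i.i.d. Gaussian noise per cycle, the values implied by the truth:
#' basal phase = `basal`, post-oligomycin = `nonmito + (1 - coupled_frac) *
#' (basal - nonmito)` (only the proton leak persists), post-FCCP = `maximal`,
#' post-rotenone/antimycin = `nonmito`. ECAR is constant at `ecar` plus
#' noise. All rates and the nuclei-stain normalization signal are multiplied
#' by the per-well cell-count `scale`.
#'
#' @param truth a [flux_truth()] object.
#' @param schedule an [injection_schedule()].
#' @param seed integer seed; identical truth + seed gives an identical plate.
#' @return An object of class `flux_plate`: list with `data` (data.frame:
#'   `well`, `cycle`, `phase`, `time_min`, `OCR`, `ECAR`), `norm_signal`
#'   (named per-well nuclei-stain intensity, arbitrary units), and the
#'   `truth` used.
#' @seealso [summarize_phases()], [analyze_flux_plate()]
#' @export
generate_flux_plate <- function(truth, schedule = injection_schedule(),
                                seed = 1L) {
  stopifnot(inherits(truth, "flux_truth"),
            inherits(schedule, "injection_schedule"))
  set.seed(as.integer(seed))
  cyc <- schedule$cycles
  phases <- rep(names(cyc), cyc)
  n_cyc <- sum(cyc)
  cycle_min <- schedule$mix_min + schedule$measure_min
  # timestamp = end of each acquisition period
  time_min <- cumsum(rep(cycle_min, n_cyc))

  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tw <- truth[i, ]
    leak <- (1 - tw$coupled_frac) * (tw$basal - tw$nonmito)
    mu <- c(basal  = tw$basal,
            oligo  = tw$nonmito + leak,
            fccp   = tw$maximal,
            rot_aa = tw$nonmito)[phases]
    ocr  <- tw$scale * mu + stats::rnorm(n_cyc, 0, tw$noise_sd)
    ecar_sd <- if (tw$basal > 0) tw$noise_sd * tw$ecar / tw$basal else 0
    ecar <- tw$scale * tw$ecar + stats::rnorm(n_cyc, 0, ecar_sd)
    data.frame(well = tw$well, cycle = seq_len(n_cyc), phase = phases,
               time_min = time_min, OCR = ocr, ECAR = ecar,
               stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, rows)
  rownames(dat) <- NULL
  # nuclei-stain (DAPI-like) signal proportional to cell count, mild noise
  norm_signal <- truth$scale * 1000 *
    exp(stats::rnorm(nrow(truth), 0, 0.01))
  names(norm_signal) <- truth$well
  structure(list(data = dat, norm_signal = norm_signal, truth = truth),
            class = "flux_plate")
}

#' Write / read a flux plate as CSV
#'
#' The on-disk dialect is long-form: columns `well`, `cycle`, `phase`,
#' `time_min`, `OCR`, `ECAR`. The per-well normalization signal travels in a
#' companion two-column CSV (`well`, `signal`).
#'
#' @param plate a `flux_plate`.
#' @param path output CSV path for the trace table.
#' @param norm_path optional path for the normalization-signal CSV.
#' @return `path`, invisibly.
#' @export
write_flux_plate <- function(plate, path, norm_path = NULL) {
  stopifnot(inherits(plate, "flux_plate"))
  utils::write.csv(plate$data, path, row.names = FALSE)
  if (!is.null(norm_path)) {
    utils::write.csv(
      data.frame(well = names(plate$norm_signal),
                 signal = unname(plate$norm_signal)),
      norm_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_flux_plate
#' @param column_map optional named character vector remapping external
#'   column names onto `well`, `cycle`, `phase`, `time_min`, `OCR`, `ECAR`
#'   (names = canonical, values = names in the file), for Wave-style
#'   exports.
#' @export
read_flux_plate <- function(path, norm_path = NULL, column_map = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(dat)[names(dat) == column_map[[canon]]] <- canon
    }
  }
  need <- c("well", "cycle", "phase", "time_min", "OCR", "ECAR")
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop("read_flux_plate: missing columns: ", paste(miss, collapse = ", "))
  }
  norm_signal <- NULL
  if (!is.null(norm_path)) {
    ns <- utils::read.csv(norm_path, stringsAsFactors = FALSE)
    norm_signal <- stats::setNames(ns$signal, ns$well)
  }
  structure(list(data = dat[need], norm_signal = norm_signal, truth = NULL),
            class = "flux_plate")
}
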