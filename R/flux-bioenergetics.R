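#' Medium and stoichiometry constants for ATP-rate partitioning
#'
#' The conversion of extracellular-flux rates (OCR, ECAR) into ATP
#' production rates needs medium chemistry (pH, the carbonic-acid pK1, the
#' buffering power of the assay medium) and pathway stoichiometry (maximum
#' H+ per O2 for complete glucose oxidation, P/O ratios, ATP per lactate).
#' None of these are measured by the analyzer itself: they are assay
#' calibration, shipped here as overridable configuration. The defaults
#' correspond to a glucose-fed assay in a HEPES-buffered medium at pH 7.4
#' (pK1 6.093 at 37 C; max H+/O2 = 1 for glucose; P/O values from the
#' standard glucose-oxidation stoichiometry: 2.486 for oxidative
#' phosphorylation, 0.121 for TCA-cycle substrate-level phosphorylation,
#' 0.242 for the glycolytic contribution tied to mitochondrial O2 use;
#' ATP/lactate = 1). Buffering power is instrument/medium-specific; the
#' default 0.1 mpH per pmol H+ must be replaced by a measured value for
#' absolute rates on a real plate. Every result carries the constants used.
#'
#' @param ph assay-medium pH.
#' @param pk1 first dissociation constant of carbonic acid (pK1).
#' @param buffering_power mpH per pmol H+ in the measurement volume.
#' @param max_h_per_o2 maximum H+ released per O2 consumed via CO2 hydration.
#' @param po_oxphos,po_tca,po_glyc P/O ratios: mol ATP per mol O atom, for
#'   oxidative phosphorylation, TCA-cycle, and glycolysis-coupled terms.
#' @param atp_per_lactate ATP per lactate extruded (glycolysis).
#' @return class `bioenergetic_constants` (named list).
#' @export
bioenergetic_constants <- function(ph = 7.4, pk1 = 6.093,
                                   buffering_power = 0.1,
                                   max_h_per_o2 = 1.0, po_oxphos = 2.486,
                                   po_tca = 0.121, po_glyc = 0.242,
                                   atp_per_lactate = 1.0) {
  k <- list(ph = ph, pk1 = pk1, buffering_power = buffering_power,
            max_h_per_o2 = max_h_per_o2, po_oxphos = po_oxphos,
            po_tca = po_tca, po_glyc = po_glyc,
            atp_per_lactate = atp_per_lactate)
  num <- unlist(k)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("bioenergetic_constants: all constants must be finite and > 0")
  }
  if (ph <= 0 || ph >= 14 || pk1 <= 0 || pk1 >= 14) {
    stop("bioenergetic_constants: pH and pK1 must lie in (0, 14)")
  }
  structure(k, class = "bioenergetic_constants")
}

phase_levels <- c("basal", "oligo", "fccp", "rot_aa")

#' Per-well respiration summary from a mito-stress-test trace
#'
#' Collapses each injection phase to a single OCR value (mean of the
#' phase's measurement cycles, or last cycle only) and derives the standard
#' respiration partition:
#' \itemize{
#'   \item `OCR_mito = OCR_tot - OCR_R/A` (mitochondrial respiration,
#'     total basal minus the rotenone/antimycin-insensitive residual);
#'   \item `OCR_coupled = OCR_tot - OCR_oligo` (oligomycin-sensitive,
#'     ATP-synthase-linked respiration);
#'   \item `OCR_leak = OCR_oligo - OCR_R/A` (proton leak), so that
#'     `OCR_coupled + OCR_leak = OCR_mito` exactly;
#'   \item `SRC_pct = OCR_max / OCR_tot x 100` (spare respiratory
#'     capacity, maximal over basal respiration as a percentage).
#' }
#' Maximal respiration is taken as the post-FCCP phase value even when it
#' falls below basal, so SRC below 100% is representable.
#'
#' @param plate a `flux_plate` (from [generate_flux_plate()] or
#'   [read_flux_plate()]).
#' @param method phase summarization: `"mean"` of all cycles in the phase
#'   (default) or `"last"` cycle only (plateau reading).
#' @return data.frame of class `respiration_summary`, one row per well:
#'   `well`, `ocr_tot`, `ocr_oligo`, `ocr_max`, `ocr_ra`, `ocr_mito`,
#'   `ocr_coupled`, `ocr_leak`, `src_pct`, `ecar_tot`.
#' @export
summarize_phases <- function(plate, method = c("mean", "last")) {
  stopifnot(inherits(plate, "flux_plate"))
  method <- match.arg(method)
  dat <- plate$data
  if (!all(dat$phase %in% phase_levels)) {
    stop("summarize_phases: unknown phase labels: ",
         paste(setdiff(unique(dat$phase), phase_levels), collapse = ", "))
  }
  if (any(!is.finite(dat$OCR)) || any(!is.finite(dat$ECAR))) {
    stop("summarize_phases: OCR and ECAR must be finite")
  }
  wells <- unique(dat$well)
  rows <- lapply(wells, function(w) {
    dw <- dat[dat$well == w, ]
    dw <- dw[order(dw$cycle), ]
    # phases must appear in injection order within the well
    ph_seq <- rle(dw$phase)$values
    if (!identical(ph_seq, phase_levels[phase_levels %in% ph_seq])) {
      stop("summarize_phases: phases out of injection order in well ", w)
    }
    val <- function(p, col = "OCR") {
      x <- dw[dw$phase == p, col]
      if (!length(x)) {
        stop("summarize_phases: well ", w, " is missing phase '", p, "'")
      }
      if (method == "mean") mean(x) else x[length(x)]
    }
    ocr_tot <- val("basal"); ocr_oligo <- val("oligo")
    ocr_max <- val("fccp"); ocr_ra <- val("rot_aa")
    data.frame(well = w, ocr_tot = ocr_tot, ocr_oligo = ocr_oligo,
               ocr_max = ocr_max, ocr_ra = ocr_ra,
               ocr_mito = ocr_tot - ocr_ra,
               ocr_coupled = ocr_tot - ocr_oligo,
               ocr_leak = ocr_oligo - ocr_ra,
               src_pct = ocr_max / ocr_tot * 100,
               ecar_tot = val("basal", "ECAR"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("respiration_summary", "data.frame")
  out
}

#' Glycolytic proton production rate from ECAR
#'
#' Total extracellular acidification has two sources: lactate extrusion by
#' glycolysis and CO2 (hydrating to HCO3- + H+) from the TCA cycle. The
#' glycolytic proton production rate removes the respiratory CO2 component:
#'
#' `PPR_glyc = ECAR_tot / BP - OCR_mito x maxH/O2 x
#'             10^(pH - pK1) / (1 + 10^(pH - pK1))`
#'
#' where BP is the medium buffering power. A negative result (possible when
#' BP or the stoichiometric constants are mis-calibrated) is returned
#' unclamped with a warning.
#'
#' @param ecar_tot total ECAR, mpH/min.
#' @param ocr_mito mitochondrial OCR, pmol O2/min.
#' @param constants a [bioenergetic_constants()] object.
#' @return PPR_glyc in pmol H+/min (vectorized over wells).
#' @export
compute_ppr_glyc <- function(ecar_tot, ocr_mito, constants = bioenergetic_constants()) {
  stopifnot(inherits(constants, "bioenergetic_constants"))
  co2_frac <- 10^(constants$ph - constants$pk1) /
    (1 + 10^(constants$ph - constants$pk1))
  ppr <- ecar_tot / constants$buffering_power -
    ocr_mito * constants$max_h_per_o2 * co2_frac
  if (any(ppr < 0, na.rm = TRUE)) {
    warning("compute_ppr_glyc: negative PPR_glyc in ", sum(ppr < 0),
            " well(s); check buffering power and CO2 constants")
  }
  ppr
}

#' Oxidative and glycolytic ATP production rates
#'
#' Partitions total cellular ATP production between oxidative
#' phosphorylation and glycolysis:
#'
#' `ATP_ox   = OCR_coupled x 2 P/O_oxphos + OCR_mito x 2 P/O_TCA`
#' `ATP_glyc = PPR_glyc x ATP/lactate + OCR_mito x 2 P/O_glyc`
#' `ATP_total = ATP_ox + ATP_glyc`
#'
#' The factor 2 converts O2 rates to O-atom rates (P/O is ATP per oxygen
#' atom). The additive identity `ATP_total = ATP_ox + ATP_glyc` holds
#' exactly by construction.
#'
#' @param summary a `respiration_summary` (per-well) data.frame.
#' @param ppr_glyc glycolytic proton production rate per well, pmol H+/min
#'   (computed with [compute_ppr_glyc()] if omitted).
#' @param constants a [bioenergetic_constants()].
#' @return data.frame of class `atp_rate_result`: `well`, `ppr_glyc`,
#'   `atp_glyc`, `atp_ox`, `atp_total`, plus the constants used as an
#'   attribute `constants`.
#' @export
compute_atp_rates <- function(summary, ppr_glyc = NULL,
                              constants = bioenergetic_constants()) {
  stopifnot(inherits(summary, "data.frame"),
            inherits(constants, "bioenergetic_constants"))
  need <- c("ocr_coupled", "ocr_mito", "ecar_tot")
  if (!all(need %in% names(summary))) {
    stop("compute_atp_rates: summary must have columns ",
         paste(need, collapse = ", "))
  }
  if (is.null(ppr_glyc)) {
    ppr_glyc <- compute_ppr_glyc(summary$ecar_tot, summary$ocr_mito, constants)
  }
  atp_ox <- summary$ocr_coupled * 2 * constants$po_oxphos +
    summary$ocr_mito * 2 * constants$po_tca
  atp_glyc <- ppr_glyc * constants$atp_per_lactate +
    summary$ocr_mito * 2 * constants$po_glyc
  out <- data.frame(well = summary$well, ppr_glyc = ppr_glyc,
                    atp_glyc = atp_glyc, atp_ox = atp_ox,
                    atp_total = atp_ox + atp_glyc,
                    stringsAsFactors = FALSE)
  attr(out, "constants") <- constants
  class(out) <- c("atp_rate_result", "data.frame")
  out
}

#' Normalize per-well rates by a cell-density signal
#'
#' Divides every rate column by the well's relative nuclei-stain signal,
#' `signal / reference`, where the reference is the mean signal across the
#' whole plate (`mode = "plate"`) or across the well's own comparison group
#' (`mode = "group"`). Units are preserved; a well with twice the average
#' cell density has its rates halved.
#'
#' @param results per-well data.frame with a `well` column; all other
#'   numeric columns are rescaled (except `src_pct`, which is a ratio of
#'   rates and is density-invariant).
#' @param signal named per-well normalization signal (> 0), e.g.
#'   `plate$norm_signal`.
#' @param mode reference for the relative signal: plate mean or group mean.
#' @param groups named per-well group labels (required for
#'   `mode = "group"`).
#' @return the rescaled data.frame.
#' @export
normalize_by_signal <- function(results, signal,
                                mode = c("plate", "group"), groups = NULL) {
  mode <- match.arg(mode)
  stopifnot("well" %in% names(results))
  sig <- signal[results$well]
  if (any(is.na(sig))) {
    stop("normalize_by_signal: no signal for well(s) ",
         paste(results$well[is.na(sig)], collapse = ", "))
  }
  if (any(sig <= 0)) {
    stop("normalize_by_signal: nonpositive signal for well(s) ",
         paste(results$well[sig <= 0], collapse = ", "))
  }
  ref <- if (mode == "plate") {
    rep(mean(sig), length(sig))
  } else {
    if (is.null(groups)) {
      stop("normalize_by_signal: mode = 'group' needs per-well groups")
    }
    g <- groups[results$well]
    stats::ave(sig, g, FUN = mean)
  }
  rel <- sig / ref
  numcols <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                     "src_pct")
  results[numcols] <- lapply(results[numcols], function(x) x / rel)
  results
}

#' Full per-well bioenergetics analysis of one flux plate
#'
#' Convenience wrapper: phase summary, PPR_glyc, ATP-rate partition, and
#' optional cell-density normalization, merged into one per-well table.
#'
#' @inheritParams summarize_phases
#' @inheritParams compute_atp_rates
#' @param normalize `"none"`, `"plate"` or `"group"` (see
#'   [normalize_by_signal()]); uses the plate's own `norm_signal`.
#' @param groups named per-well group labels, for `normalize = "group"`.
#' @return merged data.frame with summary and ATP columns; constants in
#'   attribute `constants`.
#' @export
analyze_flux_plate <- function(plate, constants = bioenergetic_constants(),
                               method = "mean", normalize = "none",
                               groups = NULL) {
  summ <- summarize_phases(plate, method = method)
  if (normalize != "none") {
    if (is.null(plate$norm_signal)) {
      stop("analyze_flux_plate: plate has no normalization signal")
    }
    summ <- normalize_by_signal(summ, plate$norm_signal, mode = normalize,
                                groups = groups)
  }
  atp <- compute_atp_rates(summ, constants = constants)
  out <- merge(summ, atp, by = "well", sort = FALSE)
  attr(out, "constants") <- constants
  out
}
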