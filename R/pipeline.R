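#' Default configuration for the end-to-end synthetic pipeline
#'
#' Describes a three-group experiment (vehicle control, alpha-synuclein
#' overexpression, alpha-synuclein + Drp1 knockdown) across every readout
#' family the package quantifies. The group effects emulate the qualitative
#' pattern such studies report — alpha-synuclein lowers coupled/maximal
#' respiration and spare respiratory capacity, fragments mitochondria
#' (higher roundness, lower aspect ratio), blocks autophagy flux (fewer
#' autolysosomes, more p62), raises the fraction of cells below the
#' membrane-potential gate — with Drp1 knockdown restoring near-control
#' values. All sizes are kept small enough for routine re-runs.
#'
#' @param groups character vector of group labels (3 by default).
#' @return nested list of stage parameters.
#' @export
pipeline_config <- function(groups = c("control", "asyn", "asyn_siDrp1")) {
  stopifnot(length(groups) == 3)
  g <- groups
  list(
    groups = g,
    flux = list(
      wells_per_group = 6, noise_sd = 5,
      truth = stats::setNames(list(
        list(basal = 100, nonmito = 20, coupled_frac = 0.75, maximal = 180,
             ecar = 20),
        list(basal = 90, nonmito = 20, coupled_frac = 0.55, maximal = 110,
             ecar = 19),
        list(basal = 98, nonmito = 20, coupled_frac = 0.72, maximal = 165,
             ecar = 20)), g),
      constants = bioenergetic_constants()
    ),
    morphometry = list(
      images_per_group = 2, n_objects = 12, size = 256,
      axes = stats::setNames(list(
        list(a = c(10, 18), b = c(3, 5)),    # tubular network
        list(a = c(5, 8), b = c(4, 6)),      # fragmented, rounded
        list(a = c(9, 16), b = c(3, 5))), g)
    ),
    tandem = list(
      tiles = c(3, 3), tile_px = 64,
      # per-cell red counts are Poisson(red_mean); each red vesicle is
      # GFP-positive (still an autophagosome) with probability green_frac
      red_mean = stats::setNames(c(12, 12, 12), g),
      green_frac = stats::setNames(c(0.33, 0.75, 0.42), g)
    ),
    cytometry = list(
      replicates = 4, n_events = 5000, q = 0.95,
      pi_high = stats::setNames(c(0.90, 0.55, 0.85), g)
    ),
    densitometry = list(
      lanes_per_group = 4, target = "p62", control = "beta-actin",
      ratios = stats::setNames(c(1.0, 2.5, 1.2), g)
    ),
    alpha = 0.05,
    analysis_unit = c(flux = "well", morphometry = "particle",
                      tandem = "cell", cytometry = "sample",
                      densitometry = "lane")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides and merges it (shallowly per stage) over
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  ov <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(ov), names(cfg))) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  cfg
}

#' Run the full synthetic pipeline: generate, quantify, test, report
#'
#' Executes every stage on freshly generated synthetic data — flux-plate
#' bioenergetics (ATP-rate partition, spare respiratory capacity),
#' mitochondrial morphometry, tandem-reporter autophagy-flux
#' classification, positive-control-gated cytometry, and densitometry
#' ratios — then runs the one-way ANOVA + Newman-Keuls layer on each
#' readout and assembles the report bundle. Fully deterministic: the same
#' `config` and `seed` reproduce the report JSON byte for byte.
#'
#' @param out_dir report output directory.
#' @param seed integer master seed; stage seeds are derived from it.
#' @param config a [pipeline_config()]-style list.
#' @return invisible list: `stages` (per-stage summaries and statistics)
#'   and `paths` (written files).
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = pipeline_config()) {
  seed <- as.integer(seed)
  g <- config$groups
  stages <- list()

  ## --- extracellular flux ---------------------------------------------
  fx <- config$flux
  truth_rows <- lapply(seq_along(g), function(i) {
    p <- fx$truth[[g[i]]]
    flux_truth(basal = p$basal, nonmito = p$nonmito,
               coupled_frac = p$coupled_frac, maximal = p$maximal,
               ecar = p$ecar, noise_sd = fx$noise_sd,
               n_wells = fx$wells_per_group)
  })
  flux_res <- do.call(rbind, lapply(seq_along(g), function(i) {
    tr <- truth_rows[[i]]
    tr$well <- paste0(g[i], "_", tr$well)
    plate <- generate_flux_plate(tr, seed = seed + 100L + i)
    res <- analyze_flux_plate(plate, constants = fx$constants)
    res$group <- g[i]
    res
  }))
  flux_summ <- do.call(rbind, lapply(split(flux_res, flux_res$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               atp_ox_mean = mean(d$atp_ox), atp_glyc_mean = mean(d$atp_glyc),
               src_pct_mean = mean(d$src_pct), stringsAsFactors = FALSE)
  }))
  rownames(flux_summ) <- NULL
  stages$flux <- list(
    summary = flux_summ,
    stats = anova_nk(data.frame(group = flux_res$group,
                                value = flux_res$atp_ox), config$alpha),
    readout = "atp_ox")

  ## --- mitochondrial morphometry --------------------------------------
  mo <- config$morphometry
  parts <- do.call(rbind, lapply(seq_along(g), function(i) {
    ax <- mo$axes[[g[i]]]
    do.call(rbind, lapply(seq_len(mo$images_per_group), function(j) {
      tr <- mito_truth(mo$n_objects, size = mo$size, a_range = ax$a,
                       b_range = ax$b, seed = seed + 200L + 10L * i + j)
      p <- measure_image(generate_mito_image(tr)$image)
      if (nrow(p)) p$group <- g[i]
      p
    }))
  }))
  morph_summ <- summarize_morphometry(parts, parts$group, min_n = 20)
  names(morph_summ)[names(morph_summ) == "n"] <- "n_particles"
  morph_summ$under_sampled <- NULL
  stages$morphometry <- list(
    summary = morph_summ,
    stats = anova_nk(data.frame(group = parts$group,
                                value = parts$roundness), config$alpha),
    readout = "roundness")

  ## --- tandem-reporter autophagy flux ----------------------------------
  td <- config$tandem
  tandem_counts <- do.call(rbind, lapply(seq_along(g), function(i) {
    n_cells <- td$tiles[1] * td$tiles[2]
    set.seed(seed + 310L + i)
    red_counts <- stats::rpois(n_cells, td$red_mean[[g[i]]])
    green_counts <- stats::rbinom(n_cells, red_counts, td$green_frac[[g[i]]])
    im <- generate_tandem_reporter_image(
      red_counts = red_counts, green_counts = green_counts,
      tiles_r = td$tiles[1], tiles_c = td$tiles[2], tile_px = td$tile_px,
      seed = seed + 300L + i)
    cfgp <- puncta_config()
    cls <- classify_tandem(detect_puncta(im$red, cfgp, im$cell_map),
                           detect_puncta(im$green, cfgp, im$cell_map),
                           cells = im$cells$cell, config = cfgp)
    cls$group <- g[i]
    cls
  }))
  tandem_summ <- summarize_puncta(
    tandem_counts[c("cell", "autophagosomes", "autolysosomes")],
    tandem_counts$group, min_n = 9)
  tandem_summ <- tandem_summ[c("group", "n_cells", "autophagosomes_mean",
                               "autophagosomes_sem", "autolysosomes_mean",
                               "autolysosomes_sem")]
  stages$tandem <- list(
    summary = tandem_summ,
    stats = anova_nk(data.frame(group = tandem_counts$group,
                                value = tandem_counts$autolysosomes),
                     config$alpha),
    readout = "autolysosomes")

  ## --- cytometry gating -------------------------------------------------
  cy <- config$cytometry
  fccp_control <- generate_cytometry_events(
    cytometry_truth(cy$n_events, pi_high = 0), seed = seed + 400L,
    label = "FCCP")
  cyto_rows <- do.call(rbind, lapply(seq_along(g), function(i) {
    pcts <- vapply(seq_len(cy$replicates), function(r) {
      s <- generate_cytometry_events(
        cytometry_truth(cy$n_events, pi_high = cy$pi_high[[g[i]]]),
        seed = seed + 400L + 10L * i + r, label = g[i])
      as.numeric(percent_above_threshold(s, fccp_control, q = cy$q))
    }, numeric(1))
    data.frame(group = g[i], replicate = seq_len(cy$replicates),
               pct_above = pcts, stringsAsFactors = FALSE)
  }))
  cyto_summ <- do.call(rbind, lapply(split(cyto_rows, cyto_rows$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               pct_above_mean = mean(d$pct_above),
               pct_above_sem = stats::sd(d$pct_above) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(cyto_summ) <- NULL
  stages$cytometry <- list(
    summary = cyto_summ,
    stats = anova_nk(data.frame(group = cyto_rows$group,
                                value = cyto_rows$pct_above), config$alpha),
    readout = "pct_above_threshold")

  ## --- densitometry -----------------------------------------------------
  de <- config$densitometry
  dtab <- generate_densitometry_table(
    unlist(de$ratios), n_lanes = de$lanes_per_group,
    target = de$target, control = de$control, seed = seed + 500L)
  dr <- ratio_to_normalizer(dtab, reference = g[1])
  names(dr$groups)[names(dr$groups) == "n"] <- "n_lanes"
  stages$densitometry <- list(
    summary = dr$groups,
    stats = anova_nk(data.frame(group = dr$units$group,
                                value = dr$units$ratio), config$alpha),
    readout = "ratio_to_control")

  ## --- report -----------------------------------------------------------
  snapshot <- config
  snapshot$flux$constants <- unclass(snapshot$flux$constants)
  snapshot$seed <- seed
  paths <- assemble_report(stages, out_dir, config = snapshot)
  invisible(list(stages = stages, paths = paths))
}
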