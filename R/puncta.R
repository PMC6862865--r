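#' Configuration for puncta (blob) detection
#'
#' Detection is multi-scale Laplacian-of-Gaussian: the image is filtered
#' with scale-normalized LoG kernels over `sigma_range`, and a punctum is a
#' local maximum of the response in space and scale that exceeds both a
#' threshold relative to the strongest response in its cell and an absolute
#' noise floor (`noise_k` times a robust estimate of the response noise).
#'
#' @param sigma_range blob scale range in px (LoG sigma; a Gaussian spot of
#'   sd t responds most strongly near sigma = t).
#' @param n_scales number of scales spanning `sigma_range`.
#' @param rel_threshold fraction of the per-cell maximum response a
#'   detection must reach.
#' @param noise_k absolute floor in units of the robust response noise sd;
#'   keeps blank cells detection-free.
#' @param match_radius pairing radius (px) for the per-vesicle tandem
#'   colocalization mode.
#' @return class `puncta_config`.
#' @export
puncta_config <- function(sigma_range = c(1, 3), n_scales = 4,
                          rel_threshold = 0.3, noise_k = 8,
                          match_radius = 3) {
  stopifnot(length(sigma_range) == 2, all(sigma_range > 0),
            sigma_range[2] >= sigma_range[1], n_scales >= 1,
            rel_threshold > 0, rel_threshold <= 1, match_radius > 0)
  structure(list(sigma_range = sigma_range, n_scales = n_scales,
                 rel_threshold = rel_threshold, noise_k = noise_k,
                 match_radius = match_radius),
            class = "puncta_config")
}

log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  G <- outer(g, g)
  G <- G / sum(G)
  r2 <- outer(x^2, x^2, "+")
  k <- G * (r2 - 2 * sigma^2) / sigma^4
  k - mean(k)  # zero-mean: flat background gives zero response
}

# Scale-normalized negative LoG response (bright blobs -> positive peaks).
log_response <- function(image, sigma) {
  eb <- EBImage::filter2(EBImage::Image(image), log_kernel(sigma))
  -sigma^2 * matrix(as.numeric(EBImage::imageData(eb)),
                    nrow(image), ncol(image))
}

is_local_max <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (m >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  res
}

#' Detect puncta in a single-channel image
#'
#' @param image numeric matrix `[row, col]`.
#' @param config a [puncta_config()].
#' @param cell_map optional integer matrix assigning pixels to cells
#'   (0 = outside any cell); detections are assigned by centroid, and the
#'   relative threshold is taken per cell. Without a map the whole frame is
#'   one cell and unmatched detections get cell `NA` ("unassigned").
#' @return data.frame of detections: `row`, `col` (0-based), `sigma`,
#'   `response`, `peak_intensity`, `cell` (integer or NA).
#' @export
detect_puncta <- function(image, config = puncta_config(), cell_map = NULL) {
  stopifnot(is.matrix(image))
  sigmas <- if (config$n_scales == 1) config$sigma_range[1] else
    exp(seq(log(config$sigma_range[1]), log(config$sigma_range[2]),
            length.out = config$n_scales))
  resp <- lapply(sigmas, function(s) log_response(image, s))
  cand <- list()
  for (i in seq_along(sigmas)) {
    lm <- is_local_max(resp[[i]])
    if (i > 1) lm <- lm & (resp[[i]] >= resp[[i - 1]])
    if (i < length(sigmas)) lm <- lm & (resp[[i]] >= resp[[i + 1]])
    idx <- which(lm & resp[[i]] > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      cand[[length(cand) + 1L]] <- data.frame(
        r = idx[, 1], c = idx[, 2], sigma = sigmas[i],
        response = resp[[i]][idx])
    }
  }
  det0 <- data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
                     response = numeric(0), peak_intensity = numeric(0),
                     cell = integer(0))
  if (!length(cand)) return(det0)
  cand <- do.call(rbind, cand)
  # noise floor from the finest-scale response map (robust sd)
  floor_abs <- config$noise_k * stats::mad(resp[[1]], center = 0)
  cell_of <- function(r, c) {
    if (is.null(cell_map)) return(rep(1L, length(r)))
    cl <- cell_map[cbind(r, c)]
    cl[cl == 0L] <- NA_integer_
    cl
  }
  cand$cell <- cell_of(cand$r, cand$c)
  # per-cell relative threshold on the response
  cellkey <- ifelse(is.na(cand$cell), 0L, cand$cell)
  cellmax <- stats::ave(cand$response, cellkey, FUN = max)
  keep <- cand$response >= pmax(config$rel_threshold * cellmax, floor_abs)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(det0)
  # non-maximum suppression across scales/space
  ord <- order(-cand$response)
  cand <- cand[ord, ]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    ki <- which(kept)
    d2 <- (cand$r[ki] - cand$r[i])^2 + (cand$c[ki] - cand$c[i])^2
    minsep <- pmax(2, sqrt(2) * pmax(cand$sigma[ki], cand$sigma[i]))
    if (all(d2 > minsep^2)) kept[i] <- TRUE
  }
  cand <- cand[kept, ]
  out <- data.frame(row = cand$r - 1, col = cand$c - 1, sigma = cand$sigma,
                    response = cand$response,
                    peak_intensity = image[cbind(cand$r, cand$c)],
                    cell = cand$cell)
  rownames(out) <- NULL
  out[order(out$cell, out$row, out$col), ]
}

#' Classify tandem-reporter vesicles into autophagosomes and autolysosomes
#'
#' The tandem mRFP-GFP-LC3 reporter marks autophagosomes in both channels
#' (yellow) while lysosomal acidity quenches GFP, leaving autolysosomes
#' red-only. The primary classification is therefore per-cell count
#' subtraction: autophagosomes = green vesicle count, autolysosomes =
#' red count - green count. A per-vesicle pairing mode (each green punctum
#' matched to the nearest red punctum within `match_radius`) is reported
#' alongside as a consistency check; summaries use the subtraction counts.
#' Cells where green exceeds red (detection asymmetry) have their
#' autolysosome count clamped at 0 and are flagged.
#'
#' @param red_detections,green_detections detection tables from
#'   [detect_puncta()] on the two channels of the same frame.
#' @param cells integer vector of cell ids to report (defaults to every
#'   cell seen in either channel).
#' @param config a [puncta_config()] (for `match_radius`).
#' @return data.frame of class `puncta_set`, one row per cell: `cell`,
#'   `red`, `green`, `autophagosomes`, `autolysosomes`, `clamped`,
#'   `paired_autophagosomes`, `paired_autolysosomes`.
#' @export
classify_tandem <- function(red_detections, green_detections, cells = NULL,
                            config = puncta_config()) {
  if (is.null(cells)) {
    cells <- sort(unique(c(red_detections$cell, green_detections$cell)))
    cells <- cells[!is.na(cells)]
  }
  rows <- lapply(cells, function(cl) {
    rd <- red_detections[!is.na(red_detections$cell) &
                           red_detections$cell == cl, , drop = FALSE]
    gd <- green_detections[!is.na(green_detections$cell) &
                             green_detections$cell == cl, , drop = FALSE]
    n_red <- nrow(rd); n_green <- nrow(gd)
    clamped <- n_green > n_red
    # secondary mode: greedy nearest-red pairing of each green punctum
    paired <- 0L
    if (n_red && n_green) {
      free <- rep(TRUE, n_red)
      for (j in seq_len(n_green)) {
        d <- sqrt((rd$row - gd$row[j])^2 + (rd$col - gd$col[j])^2)
        d[!free] <- Inf
        b <- which.min(d)
        if (is.finite(d[b]) && d[b] <= config$match_radius) {
          paired <- paired + 1L
          free[b] <- FALSE
        }
      }
    }
    data.frame(cell = cl, red = n_red, green = n_green,
               autophagosomes = n_green,
               autolysosomes = max(n_red - n_green, 0L),
               clamped = clamped,
               paired_autophagosomes = paired,
               paired_autolysosomes = n_red - paired)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell = integer(0), red = integer(0), green = integer(0),
                      autophagosomes = integer(0), autolysosomes = integer(0),
                      clamped = logical(0), paired_autophagosomes = integer(0),
                      paired_autolysosomes = integer(0))
  }
  rownames(out) <- NULL
  class(out) <- c("puncta_set", "data.frame")
  out
}

#' Count puncta per cell in a single channel
#'
#' The counting path used for p62, LC3 and proteinase-K-resistant
#' alpha-synuclein puncta: the same blob detector as [detect_puncta()],
#' aggregated to per-cell counts over the cells of `cell_map`.
#'
#' @inheritParams detect_puncta
#' @return data.frame: `cell`, `count`.
#' @export
count_puncta_per_cell <- function(image, config = puncta_config(),
                                  cell_map = NULL) {
  det <- detect_puncta(image, config, cell_map)
  cells <- if (is.null(cell_map)) 1L else
    sort(unique(as.integer(cell_map[cell_map > 0])))
  counts <- vapply(cells, function(cl) {
    sum(!is.na(det$cell) & det$cell == cl)
  }, integer(1))
  data.frame(cell = cells, count = counts)
}

#' Group summary of per-cell puncta counts
#'
#' @param counts data.frame with a `cell` column and one or more numeric
#'   count columns (e.g. the output of [classify_tandem()] or
#'   [count_puncta_per_cell()]).
#' @param groups group label per row of `counts`.
#' @param min_n flag threshold for small groups (cell-level studies
#'   typically analyze 20-50 cells per group).
#' @return data.frame: `group`, `n_cells`, then `<count>_mean` and
#'   `<count>_sem` for each count column, and `under_sampled`.
#' @export
summarize_puncta <- function(counts, groups, min_n = 20) {
  stopifnot(nrow(counts) == length(groups))
  numcols <- setdiff(names(counts)[vapply(counts, is.numeric, TRUE)], "cell")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  gs <- split(seq_len(nrow(counts)), as.character(groups))
  rows <- lapply(names(gs), function(g) {
    i <- gs[[g]]
    row <- data.frame(group = g, n_cells = length(i),
                      stringsAsFactors = FALSE)
    for (cn in numcols) {
      row[[paste0(cn, "_mean")]] <- mean(counts[[cn]][i])
      row[[paste0(cn, "_sem")]] <- sem(counts[[cn]][i])
    }
    row$under_sampled <- length(i) < min_n
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
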