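#' Planted-ellipse ground truth for synthetic mitochondria images
#'
#' Draws `n` non-overlapping ellipses with semi-axes sampled uniformly from
#' the given ranges and uniform random orientation, placed so that every
#' object lies fully inside the frame. Placement retries up to
#' `max_tries` times per object before declaring the packing infeasible.
#' By construction the true aspect ratio of an object is `a/b` and its true
#' roundness is `b/a`.
#'
#' @param n number of ellipses.
#' @param size image side length in pixels (square frame).
#' @param a_range,b_range ranges (px) for the semi-major and semi-minor
#'   axes; values are swapped per object if needed so `a >= b`.
#' @param intensity foreground intensity (arbitrary units).
#' @param background background level.
#' @param noise_sd Gaussian pixel noise sd.
#' @param min_gap minimum clearance (px) between object bounding circles.
#' @param seed integer seed.
#' @param max_tries placement attempts per object.
#' @return An object of class `mito_truth`: list with `objects` (data.frame:
#'   `id`, `a`, `b`, `theta`, `row`, `col` — centroids 0-based), `size`,
#'   `intensity`, `background`, `noise_sd`, `seed`.
#' @export
mito_truth <- function(n, size = 256, a_range = c(6, 14),
                       b_range = c(3, 8), intensity = 200,
                       background = 20, noise_sd = 5, min_gap = 3,
                       seed = 1L, max_tries = 200L) {
  stopifnot(n >= 0, size > 0, noise_sd >= 0)
  set.seed(as.integer(seed))
  objects <- data.frame(id = integer(0), a = numeric(0), b = numeric(0),
                        theta = numeric(0), row = numeric(0),
                        col = numeric(0))
  if (n > 0) {
    placed <- 0L
    rows <- cols <- radii <- aa <- bb <- th <- numeric(n)
    while (placed < n) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- stats::runif(1, a_range[1], a_range[2])
        b <- stats::runif(1, b_range[1], b_range[2])
        if (b > a) { tmp <- a; a <- b; b <- tmp }
        theta <- stats::runif(1, 0, pi)
        margin <- a + 2
        r0 <- stats::runif(1, margin, size - 1 - margin)
        c0 <- stats::runif(1, margin, size - 1 - margin)
        if (placed == 0L ||
            all(sqrt((rows[seq_len(placed)] - r0)^2 +
                     (cols[seq_len(placed)] - c0)^2) >
                radii[seq_len(placed)] + a + min_gap)) {
          placed <- placed + 1L
          rows[placed] <- r0; cols[placed] <- c0
          radii[placed] <- a; aa[placed] <- a; bb[placed] <- b
          th[placed] <- theta
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("mito_truth: could not place ", n, " objects of this size in a ",
             size, "x", size, " frame (infeasible packing)")
      }
    }
    objects <- data.frame(id = seq_len(n), a = aa, b = bb, theta = th,
                          row = rows, col = cols)
  }
  structure(list(objects = objects, size = as.integer(size),
                 intensity = intensity, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mito_truth")
}

#' Fixed-geometry variant of [mito_truth()]
#'
#' Plants exactly the ellipses given in `objects` (columns `a`, `b`,
#' `theta`, `row`, `col`; 0-based centroids) without random placement.
#' Useful for analytic oracles (e.g. one circle of known radius).
#'
#' @inheritParams mito_truth
#' @param objects data.frame of ellipse parameters.
#' @export
mito_truth_fixed <- function(objects, size = 256, intensity = 200,
                             background = 20, noise_sd = 5, seed = 1L) {
  objects <- as.data.frame(objects)
  if (nrow(objects)) {
    stopifnot(all(c("a", "b", "theta", "row", "col") %in% names(objects)))
    if (any(objects$b > objects$a) || any(objects$b <= 0)) {
      stop("mito_truth_fixed: require a >= b > 0")
    }
    inside <- objects$row - objects$a >= 0 & objects$row + objects$a <= size - 1 &
      objects$col - objects$a >= 0 & objects$col + objects$a <= size - 1
    if (!all(inside)) stop("mito_truth_fixed: objects must lie fully inside the frame")
    objects$id <- seq_len(nrow(objects))
  }
  structure(list(objects = objects, size = as.integer(size),
                 intensity = intensity, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mito_truth")
}

# Rasterize filled ellipses with subpixel edge coverage (4x4 supersampling
# per pixel, emulating partial-volume edges of real optics). Returns the
# per-pixel coverage in [0, 1] and the label map (coverage >= 0.5). Matrix
# is [row, col], 1-based internally; truth centroids are 0-based.
render_ellipses <- function(objects, size, ss = 4L) {
  labels <- matrix(0L, size, size)
  coverage <- matrix(0, size, size)
  if (!nrow(objects)) return(list(labels = labels, coverage = coverage))
  off <- (seq_len(ss) - 0.5) / ss - 0.5   # subsample offsets within a pixel
  for (i in seq_len(nrow(objects))) {
    o <- objects[i, ]
    rr <- seq(max(1, floor(o$row - o$a)), min(size, ceiling(o$row + o$a) + 1))
    cc <- seq(max(1, floor(o$col - o$a)), min(size, ceiling(o$col + o$a) + 1))
    ct <- cos(o$theta); st <- sin(o$theta)
    cov <- matrix(0, length(rr), length(cc))
    for (or in off) for (oc in off) {
      dr <- (rr - 1) + or - o$row
      dc <- (cc - 1) + oc - o$col
      u <- outer(dr, dc, function(x, y) x * ct + y * st)
      v <- outer(dr, dc, function(x, y) -x * st + y * ct)
      cov <- cov + ((u / o$a)^2 + (v / o$b)^2 <= 1)
    }
    cov <- cov / (ss * ss)
    sub_c <- coverage[rr, cc]
    coverage[rr, cc] <- pmax(sub_c, cov)
    sub_l <- labels[rr, cc]
    sub_l[cov >= 0.5] <- o$id
    labels[rr, cc] <- sub_l
  }
  list(labels = labels, coverage = coverage)
}

#' Render a synthetic single-channel mitochondria image
#'
#' Fills each planted ellipse at the truth's foreground intensity over a
#' noisy background and returns both the image and the true label map.
#'
#' @param truth a `mito_truth` object.
#' @return list with `image` (numeric matrix `[row, col]`), `labels`
#'   (integer matrix, 0 = background), `truth`.
#' @export
generate_mito_image <- function(truth) {
  stopifnot(inherits(truth, "mito_truth"))
  set.seed(truth$seed + 10000L)
  size <- truth$size
  ras <- render_ellipses(truth$objects, size)
  img <- truth$background + (truth$intensity - truth$background) * ras$coverage +
    matrix(stats::rnorm(size * size, 0, truth$noise_sd), size, size)
  list(image = img, labels = ras$labels, truth = truth)
}

#' Per-cell puncta ground truth on a rectangular cell tiling
#'
#' Cells are rectangular tiles in a `tiles_r x tiles_c` grid; each cell
#' receives the requested number of diffraction-limited spots (rendered as
#' isotropic Gaussians) at uniform random in-tile positions with a margin
#' and a minimum spot separation.
#'
#' @param counts integer vector (length `tiles_r * tiles_c`, recycled) of
#'   spots per cell.
#' @param tiles_r,tiles_c tiling of the frame into cells.
#' @param tile_px side length of one tile in pixels.
#' @param spot_sd Gaussian spot sd in px (diffraction-limited appearance).
#' @param amplitude peak spot intensity above background.
#' @param background,background_sd background level and noise sd; the
#'   signal-to-noise ratio is `amplitude / background_sd`.
#' @param min_sep minimum separation between spot centers (px).
#' @param seed integer seed.
#' @return class `puncta_truth`: list with `spots` (data.frame: `cell`,
#'   `row`, `col`, 0-based), `cells` (data.frame: `cell`, `count`),
#'   `tiles_r`, `tiles_c`, `tile_px`, rendering parameters, `seed`.
#' @export
puncta_truth <- function(counts, tiles_r = 3, tiles_c = 3, tile_px = 64,
                         spot_sd = 1.5, amplitude = 100, background = 10,
                         background_sd = 10, min_sep = 8, seed = 1L) {
  n_cells <- tiles_r * tiles_c
  counts <- rep_len(as.integer(counts), n_cells)
  stopifnot(all(counts >= 0), spot_sd > 0, background_sd >= 0)
  set.seed(as.integer(seed))
  margin <- ceiling(4 * spot_sd)
  spots <- list()
  for (cell in seq_len(n_cells)) {
    k <- counts[cell]
    if (k == 0) next
    tr <- (cell - 1) %/% tiles_c   # tile row index, 0-based
    tc <- (cell - 1) %% tiles_c
    pr <- pc <- numeric(k)
    placed <- 0L
    tries <- 0L
    while (placed < k && tries < 2000L) {
      tries <- tries + 1L
      r0 <- stats::runif(1, tr * tile_px + margin, (tr + 1) * tile_px - margin)
      c0 <- stats::runif(1, tc * tile_px + margin, (tc + 1) * tile_px - margin)
      if (placed == 0L ||
          min(sqrt((pr[seq_len(placed)] - r0)^2 +
                   (pc[seq_len(placed)] - c0)^2)) >= min_sep) {
        placed <- placed + 1L
        pr[placed] <- r0; pc[placed] <- c0
      }
    }
    if (placed < k) {
      stop("puncta_truth: cannot place ", k, " spots with min_sep ", min_sep,
           " in a ", tile_px, "px tile")
    }
    spots[[length(spots) + 1L]] <-
      data.frame(cell = cell, row = pr, col = pc)
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(cell = integer(0), row = numeric(0), col = numeric(0))
  structure(list(spots = spots,
                 cells = data.frame(cell = seq_len(n_cells), count = counts),
                 tiles_r = tiles_r, tiles_c = tiles_c, tile_px = tile_px,
                 spot_sd = spot_sd, amplitude = amplitude,
                 background = background, background_sd = background_sd,
                 seed = as.integer(seed)),
            class = "puncta_truth")
}

# Render Gaussian spots over noisy background; spots: data.frame(row, col).
render_spot_image <- function(spots, nrow_px, ncol_px, spot_sd, amplitude,
                              background, background_sd) {
  img <- matrix(background, nrow_px, ncol_px)
  half <- ceiling(4 * spot_sd)
  if (nrow(spots)) {
    for (i in seq_len(nrow(spots))) {
      r0 <- spots$row[i]; c0 <- spots$col[i]
      rr <- max(1, round(r0) - half):min(nrow_px, round(r0) + half)
      cc <- max(1, round(c0) - half):min(ncol_px, round(c0) + half)
      g <- amplitude * outer(exp(-((rr - 1) - r0)^2 / (2 * spot_sd^2)),
                             exp(-((cc - 1) - c0)^2 / (2 * spot_sd^2)))
      img[rr, cc] <- img[rr, cc] + g
    }
  }
  img + matrix(stats::rnorm(nrow_px * ncol_px, 0, background_sd),
               nrow_px, ncol_px)
}

#' Render a single-channel puncta image from ground truth
#'
#' @param truth a [puncta_truth()] object.
#' @return list with `image`, `cell_map` (integer matrix assigning every
#'   pixel to its rectangular cell), `truth`.
#' @export
generate_puncta_image <- function(truth) {
  stopifnot(inherits(truth, "puncta_truth"))
  set.seed(truth$seed + 20000L)
  nr <- truth$tiles_r * truth$tile_px
  nc <- truth$tiles_c * truth$tile_px
  img <- render_spot_image(truth$spots, nr, nc, truth$spot_sd,
                           truth$amplitude, truth$background,
                           truth$background_sd)
  list(image = img, cell_map = cell_tile_map(truth), truth = truth)
}

cell_tile_map <- function(truth) {
  nr <- truth$tiles_r * truth$tile_px
  nc <- truth$tiles_c * truth$tile_px
  tr <- (seq_len(nr) - 1) %/% truth$tile_px
  tc <- (seq_len(nc) - 1) %/% truth$tile_px
  outer(tr, tc, function(x, y) as.integer(x * truth$tiles_c + y + 1L))
}

#' Two-channel tandem mRFP-GFP-LC3 reporter image with known counts
#'
#' Plants `red_counts[i]` vesicles in cell `i`; a subset of
#' `green_counts[i]` of them also appears in the green channel (the reporter
#' topology: every GFP-positive vesicle is RFP-positive, because GFP is
#' quenched — not RFP — upon lysosome fusion). True autophagosome count per
#' cell is the green count; true autolysosome count is red minus green.
#'
#' @param red_counts,green_counts integer vectors per cell (recycled over
#'   the tiling); requires `green_counts <= red_counts` element-wise.
#' @inheritParams puncta_truth
#' @return list with `red`, `green` (image matrices), `cell_map`, `cells`
#'   (data.frame: `cell`, `red`, `green`, `autophagosomes`, `autolysosomes`),
#'   and the red-channel `truth`.
#' @export
generate_tandem_reporter_image <- function(red_counts, green_counts,
                                           tiles_r = 3, tiles_c = 3,
                                           tile_px = 64, spot_sd = 1.5,
                                           amplitude = 100, background = 10,
                                           background_sd = 10, min_sep = 8,
                                           seed = 1L) {
  n_cells <- tiles_r * tiles_c
  red_counts <- rep_len(as.integer(red_counts), n_cells)
  green_counts <- rep_len(as.integer(green_counts), n_cells)
  if (any(green_counts > red_counts)) {
    stop("generate_tandem_reporter_image: green counts must be <= red ",
         "counts (GFP+ implies RFP+)")
  }
  truth <- puncta_truth(red_counts, tiles_r, tiles_c, tile_px, spot_sd,
                        amplitude, background, background_sd, min_sep, seed)
  # first green_counts[cell] planted spots of each cell are GFP-positive
  green_spots <- do.call(rbind, lapply(seq_len(n_cells), function(cell) {
    s <- truth$spots[truth$spots$cell == cell, , drop = FALSE]
    utils::head(s, green_counts[cell])
  }))
  if (is.null(green_spots)) {
    green_spots <- truth$spots[0, ]
  }
  nr <- tiles_r * tile_px
  nc <- tiles_c * tile_px
  set.seed(truth$seed + 20000L)
  red <- render_spot_image(truth$spots, nr, nc, spot_sd, amplitude,
                           background, background_sd)
  set.seed(truth$seed + 30000L)
  green <- render_spot_image(green_spots, nr, nc, spot_sd, amplitude,
                             background, background_sd)
  cells <- data.frame(cell = seq_len(n_cells), red = red_counts,
                      green = green_counts,
                      autophagosomes = green_counts,
                      autolysosomes = red_counts - green_counts)
  list(red = red, green = green, cell_map = cell_tile_map(truth),
       cells = cells, truth = truth)
}

#' Write a (multi-)channel image as TIFF
#'
#' Intensities are rescaled to `[0, 1]` by `max_intensity` for the 16-bit
#' TIFF container. Requires the `tiff` package.
#'
#' @param channels a matrix or list of matrices (one per channel).
#' @param path output path.
#' @param max_intensity full-scale intensity.
#' @export
write_image_tiff <- function(channels, path, max_intensity = 256) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("write_image_tiff requires the 'tiff' package")
  }
  if (is.matrix(channels)) channels <- list(channels)
  imgs <- lapply(channels, function(m) pmax(pmin(m / max_intensity, 1), 0))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, max_intensity = 256) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("read_image_tiff requires the 'tiff' package")
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) m * max_intensity)
}
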