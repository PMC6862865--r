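# Shared fixture builders and scoring helpers. Everything is generated in
# code; no fixture files.

# Noise-free single-well plate with the canonical worked values.
canonical_plate <- function(noise_sd = 0, n_wells = 1, seed = 1) {
  generate_flux_plate(
    flux_truth(basal = 100, nonmito = 20, coupled_frac = 0.75,
               maximal = 180, ecar = 10, noise_sd = noise_sd,
               n_wells = n_wells),
    seed = seed)
}

# Two Gaussian spots at given centers (0-based), built independently of the
# package's renderer so detector tests have an external fixture.
two_spot_image <- function(c1, c2, size = 64, sd = 1.5, amp = 100, bg = 10) {
  idx <- seq_len(size) - 1
  g <- function(center) {
    amp * outer(exp(-(idx - center[1])^2 / (2 * sd^2)),
                exp(-(idx - center[2])^2 / (2 * sd^2)))
  }
  bg + g(c1) + g(c2)
}

# Greedy detection-vs-truth matching within a radius; returns precision,
# recall, F1.
match_f1 <- function(det, spots, radius = 3) {
  if (!nrow(det) && !nrow(spots)) return(c(precision = 1, recall = 1, f1 = 1))
  if (!nrow(det) || !nrow(spots)) return(c(precision = 0, recall = 0, f1 = 0))
  free <- rep(TRUE, nrow(spots))
  tp <- 0L
  for (i in order(-det$response)) {
    d <- sqrt((spots$row - det$row[i])^2 + (spots$col - det$col[i])^2)
    d[!free] <- Inf
    b <- which.min(d)
    if (is.finite(d[b]) && d[b] <= radius) {
      tp <- tp + 1L
      free[b] <- FALSE
    }
  }
  prec <- tp / nrow(det)
  rec <- tp / nrow(spots)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}
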