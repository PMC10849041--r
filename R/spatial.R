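## Pairwise Euclidean distance between the rows of two coordinate matrices.
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Directional nearest-neighbour distances between two point sets
#'
#' For each point of `a`, the Euclidean 3D distance to the nearest point of
#' `b`. Directional: `nn(a -> b)` need not equal `nn(b -> a)`. When the two
#' sets are the same points, set `exclude_self = TRUE` to get same-origin
#' nearest-neighbour spacing.
#'
#' @param a,b matrices or data.frames of coordinates; data.frames may use
#'   columns `x_um`, `y_um`, `z_um` or plain `x`, `y`, `z`.
#' @param exclude_self logical; drop the zero self-distance (requires
#'   `nrow(b) >= 2` and is applied positionally, so use it only when `a` and
#'   `b` are the same table).
#' @return list with `distances` (per point of `a`) and `mean`.
#' @export
nn_distances <- function(a, b, exclude_self = FALSE) {
  am <- .coord_matrix(a)
  bm <- .coord_matrix(b)
  if (nrow(bm) < 1) stop("empty reference set")
  if (exclude_self && nrow(bm) < 2)
    stop("exclude_self requires at least two reference points")
  dmat <- .cross_dist(am, bm)
  if (exclude_self) {
    if (nrow(am) != nrow(bm))
      stop("exclude_self assumes a and b are the same point set")
    diag(dmat) <- Inf
  }
  d <- apply(dmat, 1, min)
  list(distances = d, mean = mean(d))
}

.coord_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) == 2) x <- cbind(x, 0)
    return(x[, 1:3, drop = FALSE])
  }
  x <- as.data.frame(x)
  if (all(c("x_um", "y_um", "z_um") %in% names(x)))
    return(as.matrix(x[, c("x_um", "y_um", "z_um")]))
  if (all(c("x", "y", "z") %in% names(x)))
    return(as.matrix(x[, c("x", "y", "z")]))
  stop("cannot find coordinate columns (x_um/y_um/z_um or x/y/z)")
}

#' Per-channel distribution summary of assigned inputs
#'
#' Counts and percentages per channel, along-dendrite histogram of geodesic
#' soma distances in fixed-width bins, proximal/medial/distal region
#' fractions, mean soma distance, and the M1/S1 count ratio. Bins are
#' half-open `[k*w, (k+1)*w)`; regions are proximal `[0, proximal_max)`,
#' medial `[proximal_max, medial_max)`, distal `[medial_max, Inf)`.
#'
#' @param inputs assigned-input table from [filter_inputs()].
#' @param cfg an [analysis_config()].
#' @param channels channels to summarize (default M1 and S1; proportions are
#'   relative to the total over these channels).
#' @return list of class `distribution_summary`: `per_channel` (named list
#'   with `count`, `proportion_pct`, `bin_fractions`, `region_fractions`,
#'   `mean_soma_path_distance`), `total`, and `ratio_m1_s1` (NA with an
#'   `undefined` attribute when the S1 count is zero).
#' @export
distribution_summary <- function(inputs, cfg = analysis_config(),
                                 channels = c("M1", "S1")) {
  inputs <- inputs[inputs$channel %in% channels, , drop = FALSE]
  total <- nrow(inputs)
  w <- cfg$bin_width
  n_bins <- if (total) max(1, floor(max(inputs$soma_path_distance) / w) + 1) else 1
  bounds <- cfg$region_bounds
  per_channel <- lapply(channels, function(ch) {
    d <- inputs$soma_path_distance[inputs$channel == ch]
    cnt <- length(d)
    bins <- tabulate(pmin(floor(d / w), n_bins - 1) + 1, nbins = n_bins)
    names(bins) <- sprintf("%g-%g", w * (seq_len(n_bins) - 1), w * seq_len(n_bins))
    region <- c(proximal = sum(d < bounds[1]),
                medial = sum(d >= bounds[1] & d < bounds[2]),
                distal = sum(d >= bounds[2]))
    list(count = cnt,
         proportion_pct = if (total) 100 * cnt / total else NA_real_,
         bin_fractions = if (cnt) bins / cnt else bins * NA_real_,
         region_fractions = if (cnt) region / cnt else region * NA_real_,
         mean_soma_path_distance = if (cnt) mean(d) else NA_real_)
  })
  names(per_channel) <- channels
  n_m1 <- sum(inputs$channel == "M1")
  n_s1 <- sum(inputs$channel == "S1")
  ratio <- if (n_s1 > 0) n_m1 / n_s1 else
    structure(NA_real_, undefined = "S1 count is zero")
  structure(list(per_channel = per_channel, total = total,
                 ratio_m1_s1 = ratio),
            class = "distribution_summary")
}

#' Fraction of inputs with a cross-channel neighbour within a threshold
#'
#' @param a,b coordinate tables (see [nn_distances()]); the fraction is of
#'   points in `a` whose nearest point of `b` lies within `thr`
#'   (centre-to-centre, Euclidean 3D).
#' @param thr µm.
#' @return fraction in \[0, 1\].
#' @export
coloc_fraction_nn <- function(a, b, thr) {
  if (is.null(a) || nrow(.coord_matrix(a)) == 0) return(NA_real_)
  nn <- nn_distances(a, b)
  mean(nn$distances <= thr)
}

#' Colocalized fraction as a function of threshold
#'
#' @param a,b coordinate tables.
#' @param thresholds µm vector (default 1..10).
#' @return data.frame with `threshold_um` and `fraction`; non-decreasing in
#'   the threshold.
#' @export
coloc_curve <- function(a, b, thresholds = 1:10) {
  nn <- nn_distances(a, b)
  data.frame(threshold_um = thresholds,
             fraction = vapply(thresholds,
                               function(t) mean(nn$distances <= t), 0))
}

#' Test per-cell colocalized fractions against chance
#'
#' Given one colocalized fraction per cell (e.g. the fraction of S1 inputs
#' within 5 µm of an M1 input, from [coloc_fraction_nn()]), tests the
#' across-cell values against the chance level of 50% using the
#' normality-gated one-sample test of [select_and_run()].
#'
#' @param cell_fractions numeric vector, one fraction in \[0, 1\] per cell.
#' @param chance null value (default 0.5).
#' @param alpha significance level for the normality gate.
#' @return list with `mean_fraction`, `n_cells`, and `test` (a test result,
#'   or `NULL` with `skipped = TRUE` when fewer than 3 cells are available).
#' @export
coloc_vs_chance <- function(cell_fractions, chance = 0.5, alpha = 0.05) {
  cell_fractions <- cell_fractions[!is.na(cell_fractions)]
  n <- length(cell_fractions)
  if (n < 1) stop("no cells")
  res <- list(mean_fraction = mean(cell_fractions), n_cells = n,
              test = NULL, skipped = FALSE)
  if (n < 3) {
    res$skipped <- TRUE
    return(res)
  }
  res$test <- select_and_run(cell_fractions, design = "one_sample",
                             null_value = chance, alpha = alpha)
  res
}

#' Cluster summary for one cell
#'
#' Same-origin and cross-channel nearest-neighbour means, the colocalization
#' curve, and the along-dendrite distribution of clustered inputs (members of
#' cross-channel pairs within the cluster threshold).
#'
#' @param inputs assigned-input table with M1 and S1 channels.
#' @param cfg an [analysis_config()].
#' @return list of class `cluster_summary` with `nn_same` (M1->M1, S1->S1
#'   means, µm), `nn_cross` (M1->S1, S1->M1 means, µm), `coloc_fraction`
#'   (M1 and S1 fractions at the cluster threshold), `coloc_curve`
#'   (threshold 1..10 µm curves per direction), `clustered_path_bins`
#'   (bin fractions of soma path distance for clustered inputs).
#' @export
cluster_summary <- function(inputs, cfg = analysis_config()) {
  m1 <- inputs[inputs$channel == "M1", , drop = FALSE]
  s1 <- inputs[inputs$channel == "S1", , drop = FALSE]
  thr <- cfg$cluster_threshold
  w <- cfg$bin_width
  nn_mean <- function(a, b, self = FALSE) {
    if (nrow(a) == 0 || nrow(b) < (1 + self)) return(NA_real_)
    nn_distances(a, b, exclude_self = self)$mean
  }
  s1_to_m1 <- if (nrow(s1) && nrow(m1)) nn_distances(s1, m1)$distances else numeric()
  m1_to_s1 <- if (nrow(m1) && nrow(s1)) nn_distances(m1, s1)$distances else numeric()
  clustered <- rbind(
    s1[which(s1_to_m1 <= thr), , drop = FALSE],
    m1[which(m1_to_s1 <= thr), , drop = FALSE]
  )
  bins <- if (nrow(clustered)) {
    d <- clustered$soma_path_distance
    nb <- floor(max(d) / w) + 1
    b <- tabulate(floor(d / w) + 1, nbins = nb) / nrow(clustered)
    names(b) <- sprintf("%g-%g", w * (seq_len(nb) - 1), w * seq_len(nb))
    b
  } else numeric()
  structure(list(
    nn_same = c(m1_m1 = nn_mean(m1, m1, self = TRUE),
                s1_s1 = nn_mean(s1, s1, self = TRUE)),
    nn_cross = c(m1_s1 = nn_mean(m1, s1), s1_m1 = nn_mean(s1, m1)),
    coloc_fraction = c(
      m1 = if (nrow(m1) && nrow(s1)) mean(m1_to_s1 <= thr) else NA_real_,
      s1 = if (nrow(s1) && nrow(m1)) mean(s1_to_m1 <= thr) else NA_real_),
    coloc_curve = list(
      m1_to_s1 = if (nrow(m1) && nrow(s1)) coloc_curve(m1, s1) else NULL,
      s1_to_m1 = if (nrow(s1) && nrow(m1)) coloc_curve(s1, m1) else NULL),
    clustered_path_bins = bins
  ), class = "cluster_summary")
}
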