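#' Generation parameters for synthetic cells
#'
#' Bundles the planted parameters of the synthetic-data generator. Defaults
#' are the study conditions for each cell type: SPNs have ~5 primary
#' dendrites, a 14.08 µm soma, a 256.1 µm dendritic field, spiny dendrites
#' distal to the first branch point, and a between-cell distribution of the
#' M1 input proportion calibrated so that both the mean M1 percentage
#' (61.66%) and the mean of per-cell M1/S1 ratios (1.802) are matched
#' (Beta(14.95, 9.29)); FSIs have ~7 primaries, a 17.86 µm soma, a 242 µm
#' field, aspiny dendrites, and Beta(3.56, 2.91) (mean 55.05%, mean ratio
#' 1.867). Compartment placement probabilities default to the observed
#' spine/shaft/soma percentages (SPN 60.46/16.41/23.13; FSI dendrite/soma
#' 79.21/20.79). Planted AP features default to the group means (SPN HHW
#' 1.282 ms, ISI 42.11 ms, R_in 117.7 MOhm; FSI HHW 0.4043 ms, ISI
#' 13.65 ms, R_in 108.6 MOhm).
#'
#' @param cell_type `"SPN"` or `"FSI"`.
#' @param ... overrides for any default listed below.
#' @return list of class `generation_params` with fields `cell_type`,
#'   `n_primary`, `soma_diameter`, `field_diameter`, `z_scale`,
#'   `step_length`, `branch_prob_per_10um`, `spine_density`,
#'   `total_input_mean`, `prop_beta`, `compartment_probs` (spine, shaft,
#'   soma; sums to 1), `p_cluster`, `cluster_exclusive`,
#'   `background_density_per_1000um3`, `puncta_diameter_range`,
#'   `edge_offset_range`, `hhw_ms`, `isi_ms`, `rmp_mV`, `r_in_MOhm`,
#'   `threshold_mV`, `peak_mV`, `ahp_mV`.
#' @export
generation_params <- function(cell_type = c("SPN", "FSI"), ...) {
  cell_type <- match.arg(cell_type)
  p <- if (cell_type == "SPN") list(
    cell_type = "SPN",
    n_primary = 5L,
    soma_diameter = 14.08,
    field_diameter = 256.1,
    z_scale = 0.15,
    step_length = 5,
    branch_prob_per_10um = 0.22,
    spine_density = 0.5,
    total_input_mean = 352.4,
    prop_beta = c(14.95, 9.29),
    compartment_probs = c(spine = 0.6046, shaft = 0.1641, soma = 0.2313),
    p_cluster = 0,
    cluster_exclusive = TRUE,
    background_density_per_1000um3 = 0.04,
    puncta_diameter_range = c(1.0, 1.5),
    edge_offset_range = c(-0.2, 0.5),
    hhw_ms = 1.282, isi_ms = 42.11, rmp_mV = -75.0, r_in_MOhm = 117.7,
    threshold_mV = -45, peak_mV = 40, ahp_mV = -55
  ) else list(
    cell_type = "FSI",
    n_primary = 7L,
    soma_diameter = 17.86,
    field_diameter = 242.0,
    z_scale = 0.15,
    step_length = 5,
    branch_prob_per_10um = 0.28,
    spine_density = 0,
    total_input_mean = 309.6,
    prop_beta = c(3.56, 2.91),
    compartment_probs = c(spine = 0, shaft = 0.7921, soma = 0.2079),
    p_cluster = 0,
    cluster_exclusive = TRUE,
    background_density_per_1000um3 = 0.04,
    puncta_diameter_range = c(1.0, 1.5),
    edge_offset_range = c(-0.2, 0.5),
    hhw_ms = 0.4043, isi_ms = 13.65, rmp_mV = -67.94, r_in_MOhm = 108.6,
    threshold_mV = -45, peak_mV = 40, ahp_mV = -55
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  cp <- p$compartment_probs
  if (any(cp < 0) || abs(sum(cp) - 1) > 1e-6)
    stop("compartment_probs must be non-negative and sum to 1")
  if (p$p_cluster < 0 || p$p_cluster > 1) stop("p_cluster must be in [0, 1]")
  if (p$field_diameter <= p$soma_diameter)
    stop("infeasible params: field smaller than soma")
  structure(p, class = "generation_params")
}

.unit <- function(v) v / sqrt(sum(v^2))

.random_perp <- function(d) {
  ## a uniformly random unit vector perpendicular to d
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(pracma_cross(d, a))
  e2 <- pracma_cross(d, e1)
  ang <- stats::runif(1, 0, 2 * pi)
  cos(ang) * e1 + sin(ang) * e2
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic neuron morphology
#'
#' Grows `n_primary` dendritic shafts from a spherical soma by a seeded
#' stochastic branching walk (persistent direction with jitter and a slight
#' outward bias, branch probability per 10 µm of growth, radii tapering with
#' distance), flattened along z to emulate a slice reconstruction, then
#' rescales the XY extent so the caliper field diameter matches the target
#' within a few percent. For spiny cells, spine nodes (single-node heads
#' whose diameters respect the spine-detection bounds) are attached to shaft
#' nodes distal to the first branch point at the configured linear density.
#'
#' @param p a [generation_params()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `neuron_morphology` with `cell_label = p$cell_type`.
#' @export
generate_morphology <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  soma_r <- p$soma_diameter / 2
  target_R <- p$field_diameter / 2
  step <- p$step_length

  nodes <- list(c(id = 1, type = 1, x = 0, y = 0, z = 0,
                  radius = soma_r, parent = -1))
  next_id <- 2L

  ## growth cones: (attached node id, direction, radius, budget in µm)
  cones <- list()
  for (k in seq_len(p$n_primary)) {
    az <- 2 * pi * (k - 1) / p$n_primary + stats::runif(1, -0.25, 0.25)
    d <- .unit(c(cos(az), sin(az), p$z_scale * stats::rnorm(1, 0, 0.4)))
    start <- (soma_r + step / 2) * d
    nodes[[next_id]] <- c(id = next_id, type = 3, x = start[1], y = start[2],
                          z = start[3], radius = 1.1, parent = 1)
    cones[[length(cones) + 1]] <- list(node = next_id, dir = d, radius = 1.1,
                                       budget = target_R * stats::runif(1, 1.0, 1.1))
    next_id <- next_id + 1L
  }

  branch_dists <- c()  # path distances at which branch events occurred
  max_nodes <- 4000L
  while (length(cones) && next_id <= max_nodes) {
    cone <- cones[[1]]
    cones <- cones[-1]
    pos <- as.numeric(nodes[[cone$node]][c("x", "y", "z")])
    d <- cone$dir
    r <- cone$radius
    grown <- sqrt(sum(pos[1:2]^2))
    while (grown < cone$budget && next_id <= max_nodes) {
      out <- .unit(c(pos[1], pos[2], 0) + c(1e-6, 0, 0))
      d <- .unit(d + 0.25 * c(stats::rnorm(2, 0, 1), p$z_scale * stats::rnorm(1)) +
                   0.12 * out)
      pos <- pos + step * d
      r <- max(0.3, r * 0.97)
      nodes[[next_id]] <- c(id = next_id, type = 3, x = pos[1], y = pos[2],
                            z = pos[3], radius = r, parent = cone$node)
      cone$node <- next_id
      next_id <- next_id + 1L
      grown <- sqrt(sum(pos[1:2]^2))
      if (stats::runif(1) < p$branch_prob_per_10um * step / 10 &&
          grown < 0.8 * cone$budget) {
        bd <- .unit(d + 0.9 * c(stats::rnorm(2, 0, 1), p$z_scale * stats::rnorm(1)))
        cones[[length(cones) + 1]] <- list(
          node = cone$node, dir = bd, radius = r * 0.9,
          budget = cone$budget * stats::runif(1, 0.55, 0.95))
        branch_dists <- c(branch_dists, grown)
      }
    }
  }

  nd <- as.data.frame(do.call(rbind, nodes))

  ## rescale XY so the caliper field diameter hits the target
  xy <- as.matrix(nd[, c("x", "y")])
  fd <- max(stats::dist(xy[grDevices::chull(xy), , drop = FALSE]))
  sc <- p$field_diameter * stats::runif(1, 0.98, 1.02) / fd
  nd$x <- nd$x * sc
  nd$y <- nd$y * sc

  ## spines distal to the first branch point (spiny cells only)
  if (p$spine_density > 0) {
    m0 <- neuron_morphology(nd, cell_label = p$cell_type)
    first_branch <- if (length(branch_dists)) min(branch_dists) * sc else 30
    segs <- m0$segments[m0$segments$compartment == "SHAFT", ]
    eligible <- segs[m0$node_path_dist[segs$parent_node] > first_branch, ]
    nd2 <- m0$nodes[, c("id", "type", "x", "y", "z", "radius", "parent")]
    next_id <- nrow(nd2) + 1L
    spine_rows <- list()
    for (i in seq_len(nrow(eligible))) {
      n_sp <- stats::rpois(1, p$spine_density * eligible$length[i])
      if (!n_sp) next
      node_id <- eligible$child_node[i]
      npos <- as.numeric(nd2[node_id, c("x", "y", "z")])
      axis <- .unit(as.numeric(c(eligible$x1[i] - eligible$x0[i],
                                 eligible$y1[i] - eligible$y0[i],
                                 eligible$z1[i] - eligible$z0[i])))
      for (k in seq_len(n_sp)) {
        u <- .random_perp(axis)
        neck <- stats::runif(1, 0.8, 1.8)
        head_r <- stats::runif(1, 0.3, 0.6)
        spos <- npos + (nd2$radius[node_id] + neck) * u
        spine_rows[[length(spine_rows) + 1]] <-
          c(id = next_id, type = 10, x = spos[1], y = spos[2], z = spos[3],
            radius = head_r, parent = node_id)
        next_id <- next_id + 1L
      }
    }
    if (length(spine_rows))
      nd <- rbind(nd2, as.data.frame(do.call(rbind, spine_rows)))
    else nd <- nd2
  }

  neuron_morphology(nd, cell_label = p$cell_type)
}

## Sample a surface placement for one punctum on a compartment of m.
## Returns center, diameter, and the sampled attach information.
.place_on_compartment <- function(m, compartment, p) {
  rp <- stats::runif(1, p$puncta_diameter_range[1], p$puncta_diameter_range[2]) / 2
  e <- stats::runif(1, p$edge_offset_range[1], p$edge_offset_range[2])
  if (compartment == "SOMA") {
    u <- .unit(stats::rnorm(3))
    root <- as.numeric(m$nodes[1, c("x", "y", "z")])
    ctr <- root + (m$nodes$radius[1] + rp + e) * u
    return(list(center = ctr, diameter = 2 * rp))
  }
  segs <- m$segments[m$segments$compartment == compartment, , drop = FALSE]
  if (!nrow(segs)) stop("compartment ", compartment, " has zero area")
  slant <- sqrt(segs$length^2 + (segs$r0 - segs$r1)^2)
  w <- (segs$r0 + segs$r1) * slant
  i <- sample.int(nrow(segs), 1, prob = w)
  tt <- stats::runif(1)
  ax <- c(segs$x0[i], segs$y0[i], segs$z0[i]) +
    tt * c(segs$x1[i] - segs$x0[i], segs$y1[i] - segs$y0[i],
           segs$z1[i] - segs$z0[i])
  axis <- c(segs$x1[i] - segs$x0[i], segs$y1[i] - segs$y0[i],
            segs$z1[i] - segs$z0[i])
  if (sum(axis^2) == 0) axis <- c(0, 0, 1)
  u <- .random_perp(.unit(axis))
  r_loc <- segs$r0[i] + (segs$r1[i] - segs$r0[i]) * tt
  ctr <- ax + (r_loc + rp + e) * u
  list(center = ctr, diameter = 2 * rp, segment_id = segs$seg_id[i],
       fraction = tt)
}

#' Generate synthetic puncta for a morphology, with ground truth
#'
#' Per channel, the input count is Poisson with a per-cell M1 proportion
#' drawn from the configured Beta distribution (or fixed counts in
#' `fixed_counts` mode). Each input samples a compartment from the placement
#' probabilities, a surface location on that compartment (area-weighted),
#' and a radial offset making its edge distance uniform over the configured
#' range, so that every planted input passes the edge filter. With
#' probability `p_cluster` an S1 input is relocated to within the cluster
#' threshold (Euclidean, with on-surface projection) of a uniformly chosen
#' M1 input; when `cluster_exclusive` is set, the remaining S1 inputs are
#' rejection-sampled to lie beyond the cluster threshold of every M1 input,
#' so the colocalized fraction estimates `p_cluster` directly. Background
#' puncta are added at the configured volumetric density, rejection-sampled
#' to lie strictly beyond the edge threshold (clearance > threshold +
#' 0.5 µm).
#'
#' @param m a `neuron_morphology`.
#' @param p a [generation_params()].
#' @param seed integer seed or `NULL`.
#' @param fixed_counts logical; use deterministic rounded counts instead of
#'   Poisson draws (exact bookkeeping mode).
#' @param cfg an [analysis_config()] (cluster and edge thresholds).
#' @return list with `puncta` (data.frame `channel`, `x_um`, `y_um`, `z_um`,
#'   `diameter_um`) and `ground_truth` (planted per-input table with
#'   compartment, clustered flags and partner indices, per-compartment count
#'   table, the drawn M1 proportion `pi_m1`, and the generation parameters).
#' @export
generate_puncta <- function(m, p, seed = NULL, fixed_counts = FALSE,
                            cfg = analysis_config()) {
  if (!is.null(seed)) set.seed(seed)
  cp <- p$compartment_probs
  has_spine <- any(m$segments$compartment == "SPINE")
  if (cp["spine"] > 0 && !has_spine)
    stop("compartment with zero area requested: spine probability > 0 on an aspiny cell")

  pi_m1 <- stats::rbeta(1, p$prop_beta[1], p$prop_beta[2])
  if (fixed_counts) {
    n_m1 <- round(p$total_input_mean * pi_m1)
    n_s1 <- round(p$total_input_mean * (1 - pi_m1))
  } else {
    n_m1 <- stats::rpois(1, p$total_input_mean * pi_m1)
    n_s1 <- stats::rpois(1, p$total_input_mean * (1 - pi_m1))
  }

  ## a planted input must carry an unambiguous compartment label under the
  ## same spine > soma > shaft precedence the assignment applies, so
  ## locations whose punctum would also touch a higher-precedence
  ## compartment are re-drawn
  place_unambiguous <- function(compartment) {
    thr <- cfg$edge_threshold
    for (try in 1:50) {
      pl <- .place_on_compartment(m, compartment, p)
      if (compartment == "SPINE") return(pl)
      if (has_spine &&
          edge_distance(pl$center, pl$diameter, m, "SPINE")$distance <= thr)
        next
      if (compartment == "SHAFT" &&
          .soma_clearance(pl$center, pl$diameter / 2, m)$clearance <= thr)
        next
      return(pl)
    }
    pl
  }
  draw_inputs <- function(n, channel) {
    if (!n) return(NULL)
    comp <- sample(names(cp), n, replace = TRUE, prob = cp)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      pl <- place_unambiguous(toupper(comp[i]))
      rows[[i]] <- data.frame(channel = channel, x_um = pl$center[1],
                              y_um = pl$center[2], z_um = pl$center[3],
                              diameter_um = pl$diameter,
                              planted_compartment = toupper(comp[i]),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  m1 <- draw_inputs(n_m1, "M1")
  s1 <- draw_inputs(n_s1, "S1")

  clustered <- logical(if (is.null(s1)) 0 else nrow(s1))
  partner <- rep(NA_integer_, length(clustered))
  if (!is.null(s1) && !is.null(m1) && nrow(m1) > 0) {
    m1_xyz <- as.matrix(m1[, c("x_um", "y_um", "z_um")])
    thr <- cfg$cluster_threshold
    for (i in seq_len(nrow(s1))) {
      want_cluster <- stats::runif(1) < p$p_cluster
      if (want_cluster) {
        j <- sample.int(nrow(m1), 1)
        tgt <- m1_xyz[j, ]
        ok <- FALSE
        for (try in 1:25) {
          ## re-place on the tree near the chosen M1 input
          ed <- edge_distance(tgt, 0, m, setdiff(COMPARTMENTS,
                  if (has_spine) character() else "SPINE"))
          if (!is.na(ed$segment_id)) {
            seg <- m$segments[ed$segment_id, ]
            shift <- stats::runif(1, -3, 3) / max(seg$length, 1e-6)
            tt <- min(1, max(0, ed$fraction + shift))
            ax <- c(seg$x0, seg$y0, seg$z0) +
              tt * c(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
            axis <- c(seg$x1 - seg$x0, seg$y1 - seg$y0, seg$z1 - seg$z0)
            u <- .random_perp(.unit(axis))
            rp <- s1$diameter_um[i] / 2
            e <- stats::runif(1, p$edge_offset_range[1], p$edge_offset_range[2])
            r_loc <- seg$r0 + (seg$r1 - seg$r0) * tt
            cand <- ax + (r_loc + rp + e) * u
          } else {
            ## M1 attach on the soma: place nearby on the soma sphere
            root <- as.numeric(m$nodes[1, c("x", "y", "z")])
            u <- .unit(tgt - root + 2 * stats::rnorm(3, 0, 0.5))
            rp <- s1$diameter_um[i] / 2
            e <- stats::runif(1, p$edge_offset_range[1], p$edge_offset_range[2])
            cand <- root + (m$nodes$radius[1] + rp + e) * u
          }
          if (sqrt(sum((cand - tgt)^2)) <= thr - 0.2) { ok <- TRUE; break }
        }
        if (ok) {
          s1[i, c("x_um", "y_um", "z_um")] <- cand
          clustered[i] <- TRUE
          partner[i] <- j
        }
      }
      if (!clustered[i] && isTRUE(p$cluster_exclusive) && p$p_cluster > 0) {
        ## keep non-clustered S1 beyond the cluster threshold of every M1;
        ## the compartment is redrawn each try because dense compartments
        ## (e.g. a soma tiled by M1 inputs) can have no admissible location
        for (try in 1:200) {
          d <- sqrt(min(rowSums(sweep(m1_xyz, 2,
                 as.numeric(s1[i, c("x_um", "y_um", "z_um")]))^2)))
          if (d > thr) break
          comp_new <- toupper(sample(names(cp), 1, prob = cp))
          pl <- .place_on_compartment(m, comp_new, p)
          s1[i, c("x_um", "y_um", "z_um")] <- pl$center
          s1$diameter_um[i] <- pl$diameter
          s1$planted_compartment[i] <- comp_new
        }
      }
    }
  }

  planted <- rbind(
    if (!is.null(m1)) cbind(m1, clustered = FALSE, partner = NA_integer_),
    if (!is.null(s1)) cbind(s1, clustered = clustered, partner = partner)
  )

  ## background puncta: beyond the edge filter by construction
  box_lo <- apply(m$nodes[, c("x", "y", "z")], 2, min) - 5
  box_hi <- apply(m$nodes[, c("x", "y", "z")], 2, max) + 5
  vol <- prod(box_hi - box_lo)
  n_bg <- stats::rpois(1, p$background_density_per_1000um3 * vol / 1000)
  bg <- NULL
  if (n_bg > 0) {
    keep <- list()
    tries <- 0
    while (length(keep) < n_bg && tries < 50 * n_bg) {
      tries <- tries + 1
      ctr <- stats::runif(3) * (box_hi - box_lo) + box_lo
      dia <- stats::runif(1, p$puncta_diameter_range[1],
                          p$puncta_diameter_range[2])
      ed <- edge_distance(ctr, dia, m)$distance
      if (ed > cfg$edge_threshold + 0.5)
        keep[[length(keep) + 1]] <-
          data.frame(channel = sample(c("M1", "S1"), 1), x_um = ctr[1],
                     y_um = ctr[2], z_um = ctr[3], diameter_um = dia,
                     stringsAsFactors = FALSE)
    }
    if (length(keep)) bg <- do.call(rbind, keep)
  }

  puncta <- rbind(planted[, c("channel", "x_um", "y_um", "z_um", "diameter_um")],
                  bg)
  rownames(puncta) <- NULL
  counts <- if (!is.null(planted))
    table(channel = planted$channel, compartment = planted$planted_compartment)
  else table(character(), character())

  ground_truth <- list(
    params = p, pi_m1 = pi_m1, n_m1 = n_m1, n_s1 = n_s1,
    n_background = if (is.null(bg)) 0L else nrow(bg),
    planted = planted, counts = counts
  )
  list(puncta = puncta, ground_truth = ground_truth)
}

#' Audit generator ground truth against its emitted puncta
#'
#' Self-check run on every emission: planted counts match the table, every
#' clustered pair lies within the cluster threshold, and all planted inputs
#' pass the edge filter while background puncta are beyond it.
#'
#' @param gen result of [generate_puncta()].
#' @param m the `neuron_morphology` used.
#' @param cfg an [analysis_config()].
#' @return TRUE invisibly; stops with a message on any inconsistency.
#' @export
audit_ground_truth <- function(gen, m, cfg = analysis_config()) {
  gt <- gen$ground_truth
  pl <- gt$planted
  n_planted <- if (is.null(pl)) 0L else nrow(pl)
  if (n_planted + gt$n_background != nrow(gen$puncta))
    stop("ground-truth audit: punctum count mismatch")
  if (n_planted != gt$n_m1 + gt$n_s1)
    stop("ground-truth audit: channel count mismatch")
  if (n_planted) {
    cl <- which(pl$clustered)
    if (length(cl)) {
      m1_xyz <- as.matrix(pl[pl$channel == "M1", c("x_um", "y_um", "z_um")])
      for (i in cl) {
        d <- sqrt(sum((as.numeric(pl[i, c("x_um", "y_um", "z_um")]) -
                       m1_xyz[pl$partner[i], ])^2))
        if (d > cfg$cluster_threshold)
          stop("ground-truth audit: clustered pair beyond threshold")
      }
    }
    for (i in seq_len(n_planted)) {
      ed <- edge_distance(as.numeric(pl[i, c("x_um", "y_um", "z_um")]),
                          pl$diameter_um[i], m)$distance
      if (ed > cfg$edge_threshold)
        stop("ground-truth audit: planted input fails the edge filter")
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic current-step sweep set
#'
#' Replicates an 11-sweep step protocol (-500 to +500 pA in 100 pA steps,
#' 500 ms steps) at 20 kHz. Depolarizing sweeps at or above a nominal
#' rheobase carry piecewise-linear AP templates
#' (threshold -> peak -> AHP -> recovery) whose rise time lies on the sample
#' grid and whose analytic half-height width equals the planted `hhw_ms`;
#' threshold times follow the planted ISI, snapped to the sample grid.
#' Hyperpolarizing sweeps settle exponentially to the Ohmic deflection
#' `I x R_in`.
#'
#' @param p a [generation_params()].
#' @param seed integer seed or `NULL` (used only when `noise_sd_mV > 0`).
#' @param noise_sd_mV additive Gaussian noise (default 0: clean round-trip
#'   traces).
#' @param rheobase_pA smallest current that fires (default 200).
#' @return list with `sweeps` (list of `sweep_recording`) and
#'   `ground_truth` (planted threshold times per sweep, analytic HHW, the
#'   planted ISI vector, RMP, R_in).
#' @export
generate_sweeps <- function(p, seed = NULL, noise_sd_mV = 0,
                            rheobase_pA = 200) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 0.05
  onset <- 100; offset <- 600; total <- 700
  t <- seq(0, total, by = dt)
  currents <- seq(-500, 500, by = 100)
  tau <- 10

  amp <- p$peak_mV - p$threshold_mV
  drop <- p$threshold_mV - p$ahp_mV
  if (drop <= 0) stop("AHP must lie below threshold")
  t_rise <- dt * max(2, round(p$hhw_ms / dt))
  t_fall <- (p$hhw_ms - t_rise / 2) * (amp + drop) / (amp / 2)
  if (t_fall <= 0) stop("planted HHW too short for the template rise time")
  isi <- if (length(p$isi_ms) > 1) p$isi_ms else
    rep(p$isi_ms, length.out = max(3, floor((offset - onset - 40) / p$isi_ms)))
  if (any(isi <= t_rise + t_fall + 2))
    stop("planted HHW longer than the planted ISI permits")

  gt_thresholds <- list()
  sweeps <- vector("list", length(currents))
  for (si in seq_along(currents)) {
    I <- currents[si]
    v <- rep(p$rmp_mV, length(t))
    in_step <- t >= onset & t < offset
    after <- t >= offset
    if (I < rheobase_pA) {
      dV <- I * p$r_in_MOhm * 1e-3
      v[in_step] <- p$rmp_mV + dV * (1 - exp(-(t[in_step] - onset) / tau))
      v_end <- p$rmp_mV + dV * (1 - exp(-(offset - onset) / tau))
      v[after] <- p$rmp_mV + (v_end - p$rmp_mV) * exp(-(t[after] - offset) / tau)
      gt_thresholds[[si]] <- numeric()
    } else {
      ## plateau at the AP threshold voltage with a slow entry ramp
      ramp <- t >= onset & t < onset + 10
      v[ramp] <- p$rmp_mV + (p$threshold_mV - p$rmp_mV) * (t[ramp] - onset) / 10
      v[t >= onset + 10 & t < offset] <- p$threshold_mV
      v[after] <- p$rmp_mV + (p$threshold_mV - p$rmp_mV) *
        exp(-(t[after] - offset) / tau)
      thr_times <- onset + 20 + cumsum(c(0, isi))
      thr_times <- thr_times[thr_times < offset - (t_rise + t_fall + 3)]
      thr_times <- round(thr_times / dt) * dt
      for (tt in thr_times) {
        seg <- function(from, to, v0, v1) {
          sel <- t >= from & t < to
          v[sel] <<- v0 + (v1 - v0) * (t[sel] - from) / (to - from)
        }
        seg(tt, tt + t_rise, p$threshold_mV, p$peak_mV)
        seg(tt + t_rise, tt + t_rise + t_fall, p$peak_mV, p$ahp_mV)
        seg(tt + t_rise + t_fall, tt + t_rise + t_fall + 2, p$ahp_mV,
            p$threshold_mV)
      }
      gt_thresholds[[si]] <- thr_times
    }
    if (noise_sd_mV > 0) v <- v + stats::rnorm(length(v), 0, noise_sd_mV)
    sweeps[[si]] <- sweep_recording(t, v, I, onset, offset)
  }
  list(sweeps = sweeps,
       ground_truth = list(threshold_times = gt_thresholds,
                           hhw_ms = p$hhw_ms, isi_ms = isi,
                           rmp_mV = p$rmp_mV, r_in_MOhm = p$r_in_MOhm,
                           t_rise = t_rise, t_fall = t_fall))
}

#' Generate one complete synthetic cell
#'
#' Morphology, puncta (with ground-truth audit), and sweep set under a
#' single seed; optionally writes SWC, puncta CSV, sweeps CSV + metadata,
#' and ground-truth JSON into a directory.
#'
#' @param p a [generation_params()].
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @param cfg an [analysis_config()].
#' @return list with `morphology`, `puncta`, `ground_truth`, `sweeps`,
#'   `sweep_ground_truth`.
#' @export
simulate_cell <- function(p, seed, out_dir = NULL, cfg = analysis_config()) {
  set.seed(seed)
  m <- generate_morphology(p)
  gen <- generate_puncta(m, p, cfg = cfg)
  audit_ground_truth(gen, m, cfg)
  sw <- generate_sweeps(p)
  res <- list(morphology = m, puncta = gen$puncta,
              ground_truth = gen$ground_truth,
              sweeps = sw$sweeps, sweep_ground_truth = sw$ground_truth,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_swc(m, file.path(out_dir, "morphology.swc"))
    write_puncta(gen$puncta, file.path(out_dir, "puncta.csv"))
    write_sweeps(sw$sweeps, file.path(out_dir, "sweeps.csv"),
                 file.path(out_dir, "sweeps_meta.csv"))
    gt <- gen$ground_truth
    gt$params <- unclass(gt$params)
    gt$counts <- as.data.frame(gt$counts)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}
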