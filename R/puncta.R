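#' Analysis configuration
#'
#' Collects every numeric convention of the input-mapping analysis so that
#' none is hard-coded downstream. Defaults follow the conventions of the
#' underlying measurement procedure: a punctum is a putative input when its
#' edge lies within 0.5 µm of the neuron surface; cross-channel pairs within
#' 5 µm count as a cluster; along-dendrite distributions use 10 µm bins;
#' proximal/medial/distal regions split at 30 and 100 µm; automatic spine
#' detection accepts diameters between 0.6 and 2.5 µm.
#'
#' @param edge_threshold µm; inclusive clearance defining a putative input.
#' @param cluster_threshold µm; cross-channel clustering distance.
#' @param bin_width µm; width of along-dendrite distance bins.
#' @param region_bounds numeric length-2, µm: upper bound of the proximal
#'   region and upper bound of the medial region.
#' @param spine_diameter_bounds numeric length-2, µm: min/max spine diameter.
#' @param coloc_threshold_vglut µm; edge-to-edge threshold for presynaptic
#'   marker colocalization.
#' @param min_puncta_diameter µm; minimum detection diameter of a punctum.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(edge_threshold = 0.5,
                            cluster_threshold = 5,
                            bin_width = 10,
                            region_bounds = c(proximal_max = 30, medial_max = 100),
                            spine_diameter_bounds = c(0.6, 2.5),
                            coloc_threshold_vglut = 0.5,
                            min_puncta_diameter = 1) {
  cfg <- list(edge_threshold = edge_threshold,
              cluster_threshold = cluster_threshold,
              bin_width = bin_width,
              region_bounds = region_bounds,
              spine_diameter_bounds = spine_diameter_bounds,
              coloc_threshold_vglut = coloc_threshold_vglut,
              min_puncta_diameter = min_puncta_diameter)
  num <- unlist(cfg[c("edge_threshold", "cluster_threshold", "bin_width",
                      "coloc_threshold_vglut", "min_puncta_diameter")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all analysis_config thresholds must be positive")
  if (length(region_bounds) != 2 || region_bounds[1] >= region_bounds[2])
    stop("region_bounds must satisfy proximal_max < medial_max")
  if (length(spine_diameter_bounds) != 2 ||
      any(spine_diameter_bounds <= 0) ||
      spine_diameter_bounds[1] >= spine_diameter_bounds[2])
    stop("spine_diameter_bounds must be positive and increasing")
  structure(cfg, class = "analysis_config")
}

## Clearance from a sphere (center cx,cy,cz, radius rp) to every frustum in
## `segs` measured to the segment axis minus the locally interpolated radius;
## returns clearance, arc fraction, and the axis attach point.
.frustum_clearance <- function(center, rp, segs) {
  p0 <- cbind(segs$x0, segs$y0, segs$z0)
  dvec <- cbind(segs$x1 - segs$x0, segs$y1 - segs$y0, segs$z1 - segs$z0)
  l2 <- rowSums(dvec^2)
  w <- matrix(center, nrow(segs), 3, byrow = TRUE) - p0
  tt <- rowSums(w * dvec) / ifelse(l2 > 0, l2, 1)
  tt[l2 == 0] <- 0
  tt <- pmin(1, pmax(0, tt))
  ax <- p0 + dvec * tt
  d_axis <- sqrt(rowSums((ax - matrix(center, nrow(segs), 3, byrow = TRUE))^2))
  r_loc <- segs$r0 + (segs$r1 - segs$r0) * tt
  list(clearance = d_axis - r_loc - rp, fraction = tt, attach = ax)
}

## Soma clearance: sphere-to-sphere; attach point on the soma surface.
.soma_clearance <- function(center, rp, m) {
  root <- as.numeric(m$nodes[1, c("x", "y", "z")])
  rs <- m$nodes$radius[1]
  v <- center - root
  d <- sqrt(sum(v^2))
  u <- if (d > 0) v / d else c(1, 0, 0)
  list(clearance = d - rs - rp, attach = root + rs * u)
}

#' Edge distance from a punctum to the neuron surface
#'
#' Clearance between the punctum's surface and the reconstructed neuron's
#' surface: the minimum over the included frusta (and the soma sphere) of
#' the distance from the punctum centre to the nearest point on the segment
#' axis, minus the locally interpolated shaft radius, minus the punctum
#' radius. Negative values mean overlap and are legal.
#'
#' @param center numeric length-3, punctum centre (µm).
#' @param diameter punctum diameter (µm).
#' @param m a `neuron_morphology`.
#' @param subset compartments to consider (default all three).
#' @return list with `distance` (µm), `compartment`, `segment_id` (NA for the
#'   soma sphere), `fraction` (arc fraction of the attach point), `attach`
#'   (xyz of the nearest axis/surface point).
#' @export
edge_distance <- function(center, diameter, m, subset = COMPARTMENTS) {
  subset <- unique(subset)
  if (!length(subset)) stop("empty compartment subset")
  bad <- setdiff(subset, COMPARTMENTS)
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  rp <- diameter / 2
  best <- list(distance = Inf, compartment = NA_character_,
               segment_id = NA_integer_, fraction = NA_real_,
               attach = c(NA_real_, NA_real_, NA_real_))
  segs <- m$segments[m$segments$compartment %in% setdiff(subset, "SOMA"), ,
                     drop = FALSE]
  if (nrow(segs)) {
    fc <- .frustum_clearance(center, rp, segs)
    i <- which.min(fc$clearance)
    if (fc$clearance[i] < best$distance)
      best <- list(distance = fc$clearance[i],
                   compartment = segs$compartment[i],
                   segment_id = segs$seg_id[i],
                   fraction = fc$fraction[i],
                   attach = as.numeric(fc$attach[i, ]))
  }
  if ("SOMA" %in% subset) {
    sc <- .soma_clearance(center, rp, m)
    if (sc$clearance < best$distance)
      best <- list(distance = sc$clearance, compartment = "SOMA",
                   segment_id = NA_integer_, fraction = NA_real_,
                   attach = sc$attach)
  }
  if (!is.finite(best$distance))
    stop("no segments in the requested compartment subset")
  best
}

## Per-punctum, per-compartment clearances for a table of puncta.
## Returns a data.frame with one row per punctum.
.puncta_clearances <- function(puncta, m) {
  n <- nrow(puncta)
  out <- data.frame(
    d_spine = rep(Inf, n), seg_spine = NA_integer_, frac_spine = NA_real_,
    d_shaft = rep(Inf, n), seg_shaft = NA_integer_, frac_shaft = NA_real_,
    d_soma = rep(Inf, n)
  )
  spine_segs <- m$segments[m$segments$compartment == "SPINE", , drop = FALSE]
  shaft_segs <- m$segments[m$segments$compartment == "SHAFT", , drop = FALSE]
  for (i in seq_len(n)) {
    ctr <- c(puncta$x_um[i], puncta$y_um[i], puncta$z_um[i])
    rp <- puncta$diameter_um[i] / 2
    if (nrow(spine_segs)) {
      fc <- .frustum_clearance(ctr, rp, spine_segs)
      j <- which.min(fc$clearance)
      out$d_spine[i] <- fc$clearance[j]
      out$seg_spine[i] <- spine_segs$seg_id[j]
      out$frac_spine[i] <- fc$fraction[j]
    }
    if (nrow(shaft_segs)) {
      fc <- .frustum_clearance(ctr, rp, shaft_segs)
      j <- which.min(fc$clearance)
      out$d_shaft[i] <- fc$clearance[j]
      out$seg_shaft[i] <- shaft_segs$seg_id[j]
      out$frac_shaft[i] <- fc$fraction[j]
    }
    out$d_soma[i] <- .soma_clearance(ctr, rp, m)$clearance
  }
  out
}

#' Filter puncta to putative inputs and localize them
#'
#' Retains exactly the puncta whose edge distance to the neuron surface is
#' within the configured threshold (inclusive), assigns each a compartment
#' with precedence spine > soma > shaft (mirroring the subtraction order of
#' the measurement procedure: spine contacts are counted on the spine-only
#' reconstruction, somatic contacts next, the remainder are shaft contacts),
#' and records the geodesic distance from the soma at the attachment point.
#' Somatic inputs receive the Euclidean distance from the root centre to
#' their surface attach point (placing them in the first distance bin).
#'
#' @param puncta data.frame with columns `channel`, `x_um`, `y_um`, `z_um`,
#'   `diameter_um`.
#' @param m a `neuron_morphology`.
#' @param cfg an [analysis_config()].
#' @return data.frame of assigned inputs: the punctum columns plus
#'   `compartment`, `segment_id`, `fraction`, `edge_distance`,
#'   `soma_path_distance`.
#' @export
filter_inputs <- function(puncta, m, cfg = analysis_config()) {
  cols <- c("channel", "x_um", "y_um", "z_um", "diameter_um")
  empty <- data.frame(channel = character(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), diameter_um = numeric(),
                      compartment = character(), segment_id = integer(),
                      fraction = numeric(), edge_distance = numeric(),
                      soma_path_distance = numeric())
  if (is.null(puncta) || nrow(puncta) == 0) return(empty)
  if (!all(cols %in% names(puncta)))
    stop("puncta table must have columns: ", paste(cols, collapse = ", "))
  cl <- .puncta_clearances(puncta, m)
  thr <- cfg$edge_threshold
  has_spine <- any(m$segments$compartment == "SPINE")

  compartment <- ifelse(has_spine & cl$d_spine <= thr, "SPINE",
                 ifelse(cl$d_soma <= thr, "SOMA",
                 ifelse(cl$d_shaft <= thr, "SHAFT", NA_character_)))
  keep <- !is.na(compartment)
  if (!any(keep)) return(empty)

  puncta <- puncta[keep, cols, drop = FALSE]
  cl <- cl[keep, , drop = FALSE]
  compartment <- compartment[keep]

  edge_dist <- ifelse(compartment == "SPINE", cl$d_spine,
               ifelse(compartment == "SOMA", cl$d_soma, cl$d_shaft))
  seg_id <- ifelse(compartment == "SPINE", cl$seg_spine,
            ifelse(compartment == "SHAFT", cl$seg_shaft, NA_integer_))
  frac <- ifelse(compartment == "SPINE", cl$frac_spine,
          ifelse(compartment == "SHAFT", cl$frac_shaft, NA_real_))

  spd <- numeric(nrow(puncta))
  on_tree <- compartment != "SOMA"
  if (any(on_tree))
    spd[on_tree] <- path_distance(m, seg_id[on_tree], frac[on_tree])
  ## somatic inputs: Euclidean distance from root centre to the surface
  ## attach point, i.e. the soma radius
  spd[!on_tree] <- m$nodes$radius[1]

  out <- cbind(puncta,
               data.frame(compartment = compartment,
                          segment_id = as.integer(seg_id),
                          fraction = frac,
                          edge_distance = edge_dist,
                          soma_path_distance = spd))
  rownames(out) <- NULL
  out
}

#' Compartment of a single retained input
#'
#' Applies the spine > soma > shaft precedence used by [filter_inputs()] to
#' one punctum.
#'
#' @param center numeric length-3 (µm).
#' @param diameter punctum diameter (µm).
#' @param m a `neuron_morphology`.
#' @param cfg an [analysis_config()].
#' @return `"SPINE"`, `"SOMA"`, `"SHAFT"`, or `NA` if the punctum is not
#'   within the edge threshold of any compartment.
#' @export
assign_compartment <- function(center, diameter, m, cfg = analysis_config()) {
  thr <- cfg$edge_threshold
  if (any(m$segments$compartment == "SPINE") &&
      edge_distance(center, diameter, m, "SPINE")$distance <= thr)
    return("SPINE")
  if (edge_distance(center, diameter, m, "SOMA")$distance <= thr)
    return("SOMA")
  if (any(m$segments$compartment == "SHAFT") &&
      edge_distance(center, diameter, m, "SHAFT")$distance <= thr)
    return("SHAFT")
  NA_character_
}

#' Input density per 10 µm² of membrane
#'
#' Number of inputs in the requested compartments divided by the membrane
#' area of those compartments, scaled to inputs per 10 µm². For the dendrite
#' density of a spiny cell use `which = c("SHAFT", "SPINE")`.
#'
#' @param inputs assigned-input table from [filter_inputs()].
#' @param m a `neuron_morphology`.
#' @param which compartment subset.
#' @return scalar, inputs per 10 µm².
#' @export
compartment_density <- function(inputs, m, which) {
  area <- membrane_area(m, which)
  if (area <= 0) stop("zero membrane area for compartment subset")
  10 * sum(inputs$compartment %in% which) / area
}

#' Fraction of inputs colocalized with a second marker
#'
#' Fraction of rows of `a` having at least one punctum of `b` whose
#' edge-to-edge separation (centre distance minus both radii) is within
#' `thr`. Used e.g. to estimate the presynaptic-marker detection rate of
#' identified inputs.
#'
#' @param a assigned-input table (needs `x_um`, `y_um`, `z_um`, `diameter_um`).
#' @param b puncta table with the same coordinate columns.
#' @param thr µm, edge-to-edge threshold.
#' @return fraction in \[0, 1\]; `NA` (with a warning) when `a` is empty.
#' @export
coloc_fraction <- function(a, b, thr) {
  if (thr <= 0) stop("threshold must be positive")
  if (is.null(a) || nrow(a) == 0) {
    warning("empty input set; colocalized fraction undefined")
    return(NA_real_)
  }
  if (is.null(b) || nrow(b) == 0) return(0)
  am <- as.matrix(a[, c("x_um", "y_um", "z_um")])
  bm <- as.matrix(b[, c("x_um", "y_um", "z_um")])
  dmat <- .cross_dist(am, bm)
  gap <- sweep(sweep(dmat, 1, a$diameter_um / 2, "-"), 2, b$diameter_um / 2, "-")
  mean(apply(gap, 1, min) <= thr)
}
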