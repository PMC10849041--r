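#' @keywords internal
"_PACKAGE"

## Compartment vocabulary used throughout: the soma sphere, dendritic shafts,
## and dendritic spines.
COMPARTMENTS <- c("SOMA", "SHAFT", "SPINE")

#' Construct a neuron morphology from a node table
#'
#' A morphology is a rooted geometric tree of typed, radius-bearing 3D nodes
#' in micrometres: one soma root, dendritic shaft nodes, and (for spiny
#' neurons) spine nodes attached to shafts. Consecutive parent-child node
#' pairs define frustum segments whose lateral surfaces stand in for the
#' dendritic membrane; the soma is modelled as a single sphere at the root.
#'
#' Multi-node somata are merged into the largest-radius soma node, and node
#' ids are remapped to a contiguous 1..N ordering in which every parent
#' precedes its children.
#'
#' @param nodes data.frame with columns `id`, `type` (SWC integer type code),
#'   `x`, `y`, `z` (µm), `radius` (µm), `parent` (id of parent, -1 for root).
#' @param cell_label one of `"SPN"`, `"FSI"`, `"UNKNOWN"`.
#' @param spine_type_code integer SWC type code used for spine nodes
#'   (default 10; standard SWC has no spine type).
#' @param metadata optional named list (e.g. recorded position ML/AP/DV, mm).
#' @return object of class `neuron_morphology` with elements `nodes`
#'   (canonicalized node table with a `compartment` column), `segments`
#'   (frustum table: endpoints, radii, length, compartment), `node_path_dist`
#'   (geodesic distance from the root centre to every node), `cell_label`,
#'   `spine_type_code`, `metadata`.
#' @export
neuron_morphology <- function(nodes, cell_label = "UNKNOWN",
                              spine_type_code = 10L, metadata = list()) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nodes)))
    stop("node table must have columns: ", paste(req, collapse = ", "))
  nodes <- as.data.frame(nodes)[, req]
  for (col in req) nodes[[col]] <- as.numeric(nodes[[col]])
  cell_label <- match.arg(cell_label, c("SPN", "FSI", "UNKNOWN"))

  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(nodes$id == nodes$parent))
    stop("structural error: node ", nodes$id[nodes$id == nodes$parent][1],
         " is its own parent")

  accepted <- sort(unique(c(1, 3, 4, spine_type_code)))
  bad_type <- setdiff(unique(nodes$type), accepted)
  if (length(bad_type))
    stop("unknown SWC type code(s) ", paste(bad_type, collapse = ", "),
         "; accepted codes: ", paste(accepted, collapse = ", "))

  roots <- which(nodes$parent == -1)
  if (length(roots) != 1)
    stop("structural error: expected exactly one root, found ", length(roots),
         if (length(roots) > 1)
           paste0(" (nodes ", paste(nodes$id[roots], collapse = ", "), ")") else "")
  orphan <- !(nodes$parent %in% c(-1, nodes$id))
  if (any(orphan))
    stop("structural error: node ", nodes$id[which(orphan)[1]],
         " references missing parent ", nodes$parent[which(orphan)[1]])

  ## merge multi-node somata into the largest-radius soma node
  soma_rows <- which(nodes$type == 1)
  if (length(soma_rows) > 1) {
    keep <- soma_rows[which.max(nodes$radius[soma_rows])]
    keep_id <- nodes$id[keep]
    drop_ids <- setdiff(nodes$id[soma_rows], keep_id)
    nodes$parent[nodes$parent %in% drop_ids] <- keep_id
    nodes <- nodes[!(nodes$id %in% drop_ids), ]
    nodes$parent[nodes$id == keep_id] <- -1
    if (sum(nodes$parent == -1) != 1)
      stop("structural error: soma merge did not yield a single root")
  }

  ## BFS from root: canonical order, connectivity and cycle check
  id2row <- match(nodes$parent, nodes$id)
  children <- split(seq_len(nrow(nodes)), factor(id2row, levels = seq_len(nrow(nodes))))
  root_row <- which(nodes$parent == -1)
  order_rows <- integer(nrow(nodes))
  order_rows[1] <- root_row
  head <- 1L; count <- 1L
  while (head <= count) {
    kids <- children[[order_rows[head]]]
    if (length(kids)) {
      order_rows[count + seq_along(kids)] <- kids
      count <- count + length(kids)
    }
    head <- head + 1L
  }
  if (count != nrow(nodes)) {
    unreachable <- setdiff(seq_len(nrow(nodes)), order_rows[seq_len(count)])
    stop("structural error: node ", nodes$id[unreachable[1]],
         " is unreachable from the root (cycle or disconnected component)")
  }

  nodes <- nodes[order_rows, ]
  new_id <- seq_len(nrow(nodes))
  nodes$parent <- ifelse(nodes$parent == -1, -1L, new_id[match(nodes$parent, nodes$id)])
  nodes$id <- new_id
  rownames(nodes) <- NULL

  nodes$compartment <- ifelse(nodes$type == 1, "SOMA",
                       ifelse(nodes$type == spine_type_code, "SPINE", "SHAFT"))
  if (nodes$compartment[1] != "SOMA")
    stop("structural error: root node must be a soma node (type 1)")
  if (any(nodes$compartment[-1] == "SOMA"))
    stop("structural error: soma merge left a non-root soma node")
  if (any(nodes$radius[nodes$compartment %in% c("SOMA", "SHAFT")] <= 0))
    stop("radius must be > 0 for soma and shaft nodes")
  if (any(nodes$radius < 0)) stop("negative radius")

  spine_rows <- which(nodes$compartment == "SPINE")
  if (length(spine_rows)) {
    par_comp <- nodes$compartment[nodes$parent[spine_rows]]
    if (any(!par_comp %in% c("SHAFT", "SPINE")))
      stop("structural error: spine subtrees must attach to shaft nodes")
  }

  ## frustum segments: one per non-root node, typed by the child node
  ch <- nodes[-1, ]
  pa <- nodes[ch$parent, ]
  seg_len <- sqrt((ch$x - pa$x)^2 + (ch$y - pa$y)^2 + (ch$z - pa$z)^2)
  segments <- data.frame(
    seg_id = seq_len(nrow(ch)),
    parent_node = pa$id, child_node = ch$id,
    x0 = pa$x, y0 = pa$y, z0 = pa$z,
    x1 = ch$x, y1 = ch$y, z1 = ch$z,
    r0 = ifelse(pa$compartment == "SOMA" & ch$compartment == "SHAFT",
                ch$radius, pa$radius),
    r1 = ch$radius,
    length = seg_len,
    compartment = ch$compartment,
    stringsAsFactors = FALSE
  )

  node_path_dist <- numeric(nrow(nodes))
  for (i in seq_len(nrow(segments)))
    node_path_dist[segments$child_node[i]] <-
      node_path_dist[segments$parent_node[i]] + segments$length[i]

  structure(
    list(nodes = nodes, segments = segments, node_path_dist = node_path_dist,
         cell_label = cell_label, spine_type_code = as.integer(spine_type_code),
         metadata = metadata),
    class = "neuron_morphology"
  )
}

#' @export
print.neuron_morphology <- function(x, ...) {
  cat("neuron_morphology (", x$cell_label, "): ", nrow(x$nodes), " nodes, ",
      nrow(x$segments), " segments, total cable ",
      sprintf("%.1f", total_cable_length(x)), " um\n", sep = "")
  tab <- table(x$nodes$compartment)
  cat("  nodes by compartment:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a neuron morphology from an SWC file
#'
#' Accepts the standard 7-column whitespace-separated SWC dialect with `#`
#' comment lines. Type codes: 1 = soma, 3 (or 4) = dendritic shaft, and a
#' configurable custom code for spine nodes (default 10), since standard SWC
#' has no spine type.
#'
#' @param path path to SWC file.
#' @param spine_type_code integer type code flagging spine nodes.
#' @param cell_label,metadata passed to [neuron_morphology()].
#' @return a `neuron_morphology`.
#' @export
read_swc <- function(path, spine_type_code = 10L, cell_label = "UNKNOWN",
                     metadata = list()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty SWC file: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 7))
    stop("malformed SWC line (expected 7 columns): ",
         lines[which(lengths(fields) != 7)[1]])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  nodes <- data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                      z = m[, 5], radius = m[, 6], parent = m[, 7])
  neuron_morphology(nodes, cell_label = cell_label,
                    spine_type_code = spine_type_code, metadata = metadata)
}

#' Write a neuron morphology to an SWC file
#'
#' Emits sorted, contiguous 1-based ids; round-trips losslessly through
#' [read_swc()] for ids, types, coordinates, and radii.
#'
#' @param m a `neuron_morphology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  n <- m$nodes
  lines <- c(
    "# SWC export (striomap)",
    sprintf("# type codes: 1=soma, 3=dendrite shaft, %d=spine", m$spine_type_code),
    sprintf("%d %d %.10g %.10g %.10g %.10g %d",
            as.integer(n$id), as.integer(n$type), n$x, n$y, n$z, n$radius,
            as.integer(n$parent))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Total dendritic cable length
#'
#' @param m a `neuron_morphology`.
#' @param which compartments to include (default all).
#' @return scalar, µm.
#' @export
total_cable_length <- function(m, which = COMPARTMENTS) {
  sum(m$segments$length[m$segments$compartment %in% which])
}

#' Geodesic distance from the soma to a point on the tree
#'
#' Distance from the root node centre measured along the dendrite: the sum of
#' segment lengths along the unique root path plus the partial arc on the
#' addressed segment.
#'
#' @param m a `neuron_morphology`.
#' @param segment_id segment id (row of `m$segments`); vectorized.
#' @param fraction arc fraction in \[0, 1\] along the segment (0 = parent end).
#' @return distance(s) in µm.
#' @export
path_distance <- function(m, segment_id, fraction) {
  if (length(fraction) == 1) fraction <- rep(fraction, length(segment_id))
  stopifnot(length(segment_id) == length(fraction))
  if (any(is.na(segment_id)) || any(segment_id < 1) ||
      any(segment_id > nrow(m$segments)))
    stop("invalid segment id")
  if (any(fraction < 0 | fraction > 1)) stop("arc fraction must be in [0, 1]")
  seg <- m$segments[segment_id, ]
  m$node_path_dist[seg$parent_node] + fraction * seg$length
}

#' Membrane surface area by compartment
#'
#' The soma contributes the area of a sphere of the root radius; shafts and
#' spines contribute the lateral surface of their frustum segments
#' (`pi * (r0 + r1) * slant`).
#'
#' @param m a `neuron_morphology`.
#' @param which character subset of `c("SOMA", "SHAFT", "SPINE")`.
#' @return area in µm².
#' @export
membrane_area <- function(m, which = COMPARTMENTS) {
  which <- unique(which)
  if (!length(which)) {
    warning("empty compartment subset; area is 0")
    return(0)
  }
  bad <- setdiff(which, COMPARTMENTS)
  if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
  area <- 0
  if ("SOMA" %in% which)
    area <- area + 4 * pi * m$nodes$radius[1]^2
  seg <- m$segments[m$segments$compartment %in% setdiff(which, "SOMA"), ]
  if (nrow(seg)) {
    slant <- sqrt(seg$length^2 + (seg$r0 - seg$r1)^2)
    area <- area + sum(pi * (seg$r0 + seg$r1) * slant)
  }
  area
}

#' Morphometric summary of a reconstructed neuron
#'
#' @param m a `neuron_morphology`.
#' @return list with `primary_dendrite_count` (shaft children of the root),
#'   `soma_diameter` (2 x root radius, µm), `field_diameter` (largest pairwise
#'   distance among node XY projections, µm — the caliper diameter of the
#'   dendritic field on a maximum projection), `z_range` (max z - min z, µm),
#'   `total_cable_length` (µm), `n_spines` (spine node count).
#' @export
morphometrics <- function(m) {
  n <- m$nodes
  kids <- which(n$parent == 1)
  primary <- sum(n$compartment[kids] == "SHAFT")
  xy <- cbind(n$x, n$y)
  if (nrow(xy) > 1) {
    ## caliper diameter; convex hull first for large trees (same maximum)
    if (nrow(xy) > 500) {
      h <- tryCatch(grDevices::chull(xy), error = function(e) seq_len(nrow(xy)))
      xy <- xy[h, , drop = FALSE]
    }
    fd <- max(stats::dist(xy))
  } else fd <- 0
  list(
    primary_dendrite_count = primary,
    soma_diameter = 2 * n$radius[1],
    field_diameter = fd,
    z_range = max(n$z) - min(n$z),
    total_cable_length = total_cable_length(m),
    n_spines = sum(n$compartment == "SPINE")
  )
}
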