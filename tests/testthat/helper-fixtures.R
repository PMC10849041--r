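# Fixtures built in code: tiny hand-made morphologies, random trees, and
# piecewise-linear AP traces used across the test files.

## root + straight chain along x, then a turn along y:
## root(0,0,0) - a(10,0,0) - b(10,5,0)
chain_morphology <- function(shaft_radius = 0.5, soma_radius = 2) {
  neuron_morphology(data.frame(
    id = 1:3, type = c(1, 3, 3),
    x = c(0, 10, 10), y = c(0, 0, 5), z = 0,
    radius = c(soma_radius, shaft_radius, shaft_radius),
    parent = c(-1, 1, 2)
  ))
}

## a straight shaft with one spine on node 3
spiny_chain <- function() {
  neuron_morphology(data.frame(
    id = 1:5, type = c(1, 3, 3, 3, 10),
    x = c(0, 10, 20, 30, 20), y = c(0, 0, 0, 0, 2), z = 0,
    radius = c(3, 0.5, 0.5, 0.5, 0.4),
    parent = c(-1, 1, 2, 3, 3)
  ))
}

## random valid tree: parents drawn among earlier nodes, shafts only
random_tree <- function(n, seed, spread = 50) {
  set.seed(seed)
  nodes <- data.frame(
    id = seq_len(n),
    type = c(1, rep(3, n - 1)),
    x = c(0, stats::runif(n - 1, -spread, spread)),
    y = c(0, stats::runif(n - 1, -spread, spread)),
    z = c(0, stats::runif(n - 1, -spread / 4, spread / 4)),
    radius = c(4, stats::runif(n - 1, 0.3, 1.2)),
    parent = c(-1, vapply(2:n, function(i) sample.int(i - 1, 1), 0L))
  )
  neuron_morphology(nodes)
}

## flat sweep at a holding voltage
flat_sweep <- function(v = -75, current = 300) {
  t <- seq(0, 700, by = 0.05)
  sweep_recording(t, rep(v, length(t)), current, 100, 600)
}

## sweep with piecewise-linear AP templates at given threshold times (ms);
## rise/fall in ms, baseline at threshold voltage
template_sweep <- function(thr_times, rise = 0.5, fall = 0.5,
                           thr_v = -45, peak_v = 40, ahp_v = -55,
                           recover = 2, current = 300) {
  t <- seq(0, 700, by = 0.05)
  v <- rep(thr_v, length(t))
  v[t < 100] <- -75
  for (tt in thr_times) {
    seg <- function(from, to, v0, v1) {
      sel <- t >= from & t < to
      v[sel] <<- v0 + (v1 - v0) * (t[sel] - from) / (to - from)
    }
    seg(tt, tt + rise, thr_v, peak_v)
    seg(tt + rise, tt + rise + fall, peak_v, ahp_v)
    seg(tt + rise + fall, tt + rise + fall + recover, ahp_v, thr_v)
  }
  sweep_recording(t, v, current, 100, 600)
}

## independent brute-force oracle: min surface clearance of a sphere to a
## morphology, looping over segments with scalar arithmetic (plus the soma
## sphere); deliberately a different formulation from the implementation
brute_edge_distance <- function(center, diameter, m) {
  rp <- diameter / 2
  root <- as.numeric(m$nodes[1, c("x", "y", "z")])
  best <- sqrt(sum((center - root)^2)) - m$nodes$radius[1] - rp
  for (i in seq_len(nrow(m$segments))) {
    s <- m$segments[i, ]
    p0 <- c(s$x0, s$y0, s$z0); p1 <- c(s$x1, s$y1, s$z1)
    d <- p1 - p0
    L2 <- sum(d^2)
    tt <- if (L2 > 0) sum((center - p0) * d) / L2 else 0
    tt <- min(1, max(0, tt))
    ax <- p0 + tt * d
    clear <- sqrt(sum((center - ax)^2)) - (s$r0 + (s$r1 - s$r0) * tt) - rp
    if (clear < best) best <- clear
  }
  best
}
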