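test_that("edge distance follows exact sphere-to-frustum geometry", {
  m <- chain_morphology(shaft_radius = 0.5, soma_radius = 2)
  ## center on the shaft axis, shaft radius 0.5, punctum diameter 1:
  ## clearance = 0 - 0.5 - 0.5 = -1 (inside)
  d <- edge_distance(c(5, 0, 0), 1, m, subset = "SHAFT")
  expect_equal(d$distance, -1.0, tolerance = 1e-12)
  ## 2 um off-axis, radius 0.5 shaft, 0.5 punctum: 2 - 0.5 - 0.5 = 1
  d2 <- edge_distance(c(5, 2, 0), 1, m, subset = "SHAFT")
  expect_equal(d2$distance, 1.0, tolerance = 1e-12)
  expect_equal(d2$fraction, 0.5, tolerance = 1e-9)
  expect_error(edge_distance(c(0, 0, 0), 1, m, subset = character()), "empty")
})

test_that("edge distance equals the exhaustive per-segment scan", {
  m <- random_tree(80, seed = 21)
  set.seed(22)
  n <- 200
  centers <- cbind(runif(n, -60, 60), runif(n, -60, 60), runif(n, -20, 20))
  dia <- runif(n, 1, 1.5)
  for (i in seq_len(n)) {
    got <- edge_distance(centers[i, ], dia[i], m)$distance
    expect_equal(got, brute_edge_distance(centers[i, ], dia[i], m),
                 tolerance = 1e-9)
  }
})

test_that("the input filter is inclusive at the threshold and idempotent", {
  m <- chain_morphology(shaft_radius = 0.5)
  mk <- function(y) data.frame(channel = "M1", x_um = 5, y_um = y, z_um = 0,
                               diameter_um = 1)
  ## edge distance = y - 0.5 - 0.5; y = 1.5 -> exactly 0.5 (retained)
  expect_equal(nrow(filter_inputs(mk(1.5), m)), 1)
  expect_equal(filter_inputs(mk(1.5), m)$edge_distance, 0.5, tolerance = 1e-12)
  expect_equal(nrow(filter_inputs(mk(1.51), m)), 0)
  expect_equal(nrow(filter_inputs(mk(1.5)[0, ], m)), 0)

  ## idempotence: filtering the retained set again keeps it unchanged
  p <- rbind(mk(1.2), mk(0.9), mk(3))
  f1 <- filter_inputs(p, m)
  f2 <- filter_inputs(f1[, names(p)], m)
  expect_equal(f1, f2)

  ## retained set grows monotonically with the threshold
  p2 <- do.call(rbind, lapply(seq(0.8, 3, by = 0.2), mk))
  ns <- vapply(c(0.25, 0.5, 1, 2),
               function(thr) nrow(filter_inputs(p2, m,
                 analysis_config(edge_threshold = thr))), 0L)
  expect_true(all(diff(ns) >= 0))
})

test_that("compartment precedence is spine > soma > shaft", {
  m <- spiny_chain()
  ## punctum between the spine head and its parent shaft: touches both
  expect_equal(assign_compartment(c(20, 1.2, 0), 1, m), "SPINE")
  ## punctum touching the soma only
  expect_equal(assign_compartment(c(0, 3.6, 0), 1, m), "SOMA")
  ## far shaft punctum
  expect_equal(assign_compartment(c(30, 1.2, 0), 1, m), "SHAFT")
  ## out of reach
  expect_true(is.na(assign_compartment(c(0, 50, 0), 1, m)))
})

test_that("compartment labels partition the retained inputs on synthetic cells", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    p <- generation_params(if (seed %% 2) "SPN" else "FSI")
    m <- generate_morphology(p)
    gen <- generate_puncta(m, p)
    inputs <- filter_inputs(gen$puncta, m)
    tab <- table(factor(inputs$compartment, levels = c("SPINE", "SOMA", "SHAFT")))
    expect_identical(sum(tab), nrow(inputs))
    expect_true(all(inputs$edge_distance <= 0.5 + 1e-12))
    ## somatic inputs sit within one soma radius (+ threshold) of the root
    som <- inputs[inputs$compartment == "SOMA", ]
    if (nrow(som))
      expect_true(all(som$soma_path_distance <= m$nodes$radius[1] + 0.5))
  }
})

test_that("densities are counts per 10 um^2 of membrane", {
  ## soma area 4*pi*r^2 = 100 -> r = sqrt(100/(4*pi))
  r <- sqrt(100 / (4 * pi))
  m <- neuron_morphology(data.frame(
    id = 1:2, type = c(1, 3), x = c(0, 10), y = 0, z = 0,
    radius = c(r, 0.5), parent = c(-1, 1)))
  inputs <- data.frame(compartment = rep("SOMA", 5))
  expect_equal(compartment_density(inputs, m, "SOMA"), 0.5, tolerance = 1e-12)
  ## linear in the count
  expect_equal(compartment_density(rbind(inputs, inputs), m, "SOMA"), 1.0,
               tolerance = 1e-12)
  expect_error(compartment_density(inputs, m, "SPINE"), "zero membrane area")
})

test_that("marker colocalization is edge-to-edge", {
  a <- data.frame(x_um = c(0, 10), y_um = 0, z_um = 0, diameter_um = 1)
  expect_equal(coloc_fraction(a, a[0, ], 0.5), 0)
  expect_equal(coloc_fraction(a, a, 0.5), 1)  # same coordinates
  ## centers 2 um apart, radii 0.5 each: gap 1.0
  b <- data.frame(x_um = 2, y_um = 0, z_um = 0, diameter_um = 1)
  expect_equal(coloc_fraction(a, b, 1.0), 0.5)
  expect_equal(coloc_fraction(a, b, 0.9), 0)
  expect_warning(out <- coloc_fraction(a[0, ], b, 0.5), "empty")
  expect_true(is.na(out))
})
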