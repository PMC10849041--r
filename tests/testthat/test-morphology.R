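test_that("SWC reading builds a validated tree and round-trips losslessly", {
  swc <- tempfile(fileext = ".swc")
  writeLines(c("# minimal tree",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 10 5 0 0.8 2"), swc)
  m <- read_swc(swc)
  expect_s3_class(m, "neuron_morphology")
  expect_equal(nrow(m$segments), 2)
  expect_equal(total_cable_length(m), 15)

  out <- tempfile(fileext = ".swc")
  write_swc(m, out)
  m2 <- read_swc(out)
  expect_identical(m$nodes, m2$nodes)

  ## a second write of the same morphology is byte-identical
  out2 <- tempfile(fileext = ".swc")
  write_swc(m, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("structural defects are rejected with informative errors", {
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 2"), bad)
  expect_error(read_swc(bad), "own parent")

  writeLines(c("1 1 0 0 0 5 -1", "2 1 9 0 0 5 -1"), bad)
  expect_error(read_swc(bad), "exactly one root")

  writeLines(c("1 1 0 0 0 5 -1", "2 7 1 0 0 1 1"), bad)
  expect_error(read_swc(bad), "accepted codes")

  ## cycle between nodes 2 and 3
  expect_error(
    neuron_morphology(data.frame(id = 1:3, type = c(1, 3, 3),
                                 x = 0:2, y = 0, z = 0, radius = 1,
                                 parent = c(-1, 3, 2))),
    "unreachable")
})

test_that("multi-node somata merge to the largest-radius node", {
  m <- neuron_morphology(data.frame(
    id = 1:4, type = c(1, 1, 3, 3),
    x = c(0, 2, 10, 20), y = 0, z = 0,
    radius = c(3, 5, 1, 1),
    parent = c(-1, 1, 2, 3)))
  expect_equal(sum(m$nodes$compartment == "SOMA"), 1)
  expect_equal(m$nodes$radius[1], 5)
})

test_that("path_distance sums segment lengths along the root path", {
  m <- chain_morphology()
  ## end of second segment: 10 + 5
  expect_equal(path_distance(m, 2, 1), 15)
  ## start of first segment is the root itself
  expect_equal(path_distance(m, 1, 0), 0)
  expect_equal(path_distance(m, 1, 0.5), 5)
})

test_that("path_distance matches a brute-force root-path walk on random trees", {
  for (seed in c(11, 12)) {
    m <- random_tree(50, seed)
    for (sid in seq_len(nrow(m$segments))) {
      ## oracle: explicitly walk parents from the segment's child node
      node <- m$segments$child_node[sid]
      d <- 0
      while (node != 1) {
        row <- m$segments[m$segments$child_node == node, ]
        d <- d + row$length
        node <- row$parent_node
      }
      expect_equal(path_distance(m, sid, 1), d, tolerance = 1e-12)
      ## and never beyond the total cable
      expect_lte(path_distance(m, sid, 1), total_cable_length(m) + 1e-9)
    }
  }
})

test_that("membrane areas follow sphere and frustum closed forms", {
  ## soma sphere of radius 7.04 um
  m <- neuron_morphology(data.frame(
    id = 1:2, type = c(1, 3), x = c(0, 10), y = 0, z = 0,
    radius = c(7.04, 1), parent = c(-1, 1)))
  expect_equal(membrane_area(m, "SOMA"), 4 * pi * 7.04^2, tolerance = 1e-12)
  ## single cylindrical segment length 10, radius 1
  expect_equal(membrane_area(m, "SHAFT"), 2 * pi * 1 * 10, tolerance = 1e-12)
  ## doubling all radii multiplies soma area by 4
  m2 <- neuron_morphology(data.frame(
    id = 1:2, type = c(1, 3), x = c(0, 10), y = 0, z = 0,
    radius = c(14.08, 2), parent = c(-1, 1)))
  expect_equal(membrane_area(m2, "SOMA") / membrane_area(m, "SOMA"), 4,
               tolerance = 1e-12)
  ## additivity over compartments is exact
  sp <- spiny_chain()
  expect_identical(membrane_area(sp),
                   membrane_area(sp, "SOMA") + membrane_area(sp, "SHAFT") +
                     membrane_area(sp, "SPINE"))
  expect_warning(a0 <- membrane_area(sp, character()), "empty")
  expect_equal(a0, 0)
})

test_that("morphometrics reports primaries, field diameter and z-range", {
  m <- neuron_morphology(data.frame(
    id = 1:3, type = c(1, 3, 3),
    x = c(0, 10, 10), y = c(0, 0, 5), z = c(0, 2, 7),
    radius = c(3, 1, 1), parent = c(-1, 1, 2)))
  mm <- morphometrics(m)
  ## brute-force pairwise XY maximum: (0,0),(10,0),(10,5) -> sqrt(125)
  expect_equal(mm$field_diameter, sqrt(125), tolerance = 1e-12)
  expect_equal(mm$z_range, 7)
  expect_equal(mm$primary_dendrite_count, 1)
  expect_equal(mm$soma_diameter, 6)

  single <- neuron_morphology(data.frame(id = 1, type = 1, x = 0, y = 0,
                                         z = 0, radius = 2, parent = -1))
  expect_equal(morphometrics(single)$field_diameter, 0)
  expect_equal(morphometrics(single)$z_range, 0)
})
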