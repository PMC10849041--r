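test_that("morphology generation is deterministic and hits its targets", {
  p <- generation_params("SPN")
  m1 <- generate_morphology(p, seed = 7)
  m2 <- generate_morphology(p, seed = 7)
  f1 <- tempfile(fileext = ".swc"); f2 <- tempfile(fileext = ".swc")
  write_swc(m1, f1); write_swc(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  mm <- morphometrics(m1)
  expect_equal(mm$primary_dendrite_count, 5)
  expect_equal(mm$soma_diameter, 14.08)
  expect_lt(abs(mm$field_diameter - 256.1) / 256.1, 0.1)
  expect_gt(mm$n_spines, 0)

  fsi <- generate_morphology(generation_params("FSI"), seed = 8)
  expect_equal(morphometrics(fsi)$primary_dendrite_count, 7)
  expect_equal(morphometrics(fsi)$n_spines, 0)

  expect_error(generation_params("SPN", field_diameter = 10), "infeasible")
})

test_that("planted puncta pass the filter; background does not", {
  recovered <- vapply(c(61, 62, 63), function(seed) {
    set.seed(seed)
    p <- generation_params("SPN")
    m <- generate_morphology(p)
    gen <- generate_puncta(m, p)
    audit_ground_truth(gen, m)
    gt <- gen$ground_truth
    ## bookkeeping: planted counts equal ground-truth totals exactly
    expect_identical(nrow(gt$planted), gt$n_m1 + gt$n_s1)
    expect_identical(nrow(gen$puncta), nrow(gt$planted) + gt$n_background)
    inputs <- filter_inputs(gen$puncta, m)
    ## no background punctum can be retained (clearance > threshold + 0.5)
    expect_lte(nrow(inputs), nrow(gt$planted))
    nrow(inputs) / nrow(gt$planted)
  }, 0)
  expect_true(all(recovered >= 0.99))
})

test_that("fixed-count mode gives deterministic channel totals", {
  p <- generation_params("FSI", prop_beta = c(1e9, 1e9))  # pi -> 0.5
  set.seed(64)
  m <- generate_morphology(p)
  gen <- generate_puncta(m, p, fixed_counts = TRUE)
  expect_equal(gen$ground_truth$n_m1, round(309.6 * gen$ground_truth$pi_m1))
  expect_error(
    generate_puncta(m, generation_params("FSI",
      compartment_probs = c(spine = 0.5, shaft = 0.3, soma = 0.2))),
    "zero area")
})

test_that("clustered S1 inputs land within the cluster threshold", {
  set.seed(65)
  p <- generation_params("SPN", p_cluster = 0.8)
  m <- generate_morphology(p)
  gen <- generate_puncta(m, p)
  audit_ground_truth(gen, m)
  pl <- gen$ground_truth$planted
  s1 <- pl[pl$channel == "S1", ]
  m1 <- pl[pl$channel == "M1", c("x_um", "y_um", "z_um")]
  nn <- nn_distances(s1[, c("x_um", "y_um", "z_um")], m1)$distances
  ## planted clustered inputs are within 5 um; the rest were rejected beyond
  expect_true(all(nn[s1$clustered] <= 5))
  expect_true(all(nn[!s1$clustered] > 5))
  expect_gt(mean(s1$clustered), 0.6)
})

test_that("sweep generation round-trips the planted AP features", {
  for (ct in c("SPN", "FSI")) {
    p <- generation_params(ct)
    sw <- generate_sweeps(p)
    expect_length(sw$sweeps, 11)
    expect_equal(vapply(sw$sweeps, function(s) s$current_pA, 0),
                 seq(-500, 500, by = 100))
    s <- sw$sweeps[[11]]
    ev <- detect_aps(s)
    ## extracted threshold times equal the planted (grid-snapped) times
    expect_identical(ev$threshold_time, sw$ground_truth$threshold_times[[11]])
    ## HHW recovered at interpolation resolution
    hh <- vapply(seq_len(nrow(ev)), function(k) compute_hhw(s, ev[k, ]), 0)
    expect_equal(hh, rep(p$hhw_ms, length(hh)), tolerance = 1e-9)
    ## train features agree with the planted ISIs exactly
    f <- compute_train_features(ev)
    expect_identical(f$isi_ms, diff(sw$ground_truth$threshold_times[[11]]))
  }
  expect_error(generate_sweeps(generation_params("FSI", isi_ms = 0.5)),
               "ISI")
})

test_that("the sweep-set extractor classifies both cell types correctly", {
  f_spn <- extract_features(generate_sweeps(generation_params("SPN"))$sweeps)
  f_fsi <- extract_features(generate_sweeps(generation_params("FSI"))$sweeps)
  expect_equal(f_spn$cell_class, "SPN")
  expect_equal(f_fsi$cell_class, "FSI")
  expect_true(f_spn$steady_state && f_fsi$steady_state)
  ## planted mean IFF: 1000 / 13.65 = 73.26 Hz for the FSI
  expect_equal(f_fsi$mean_iff_hz, 1000 / 13.65, tolerance = 0.005)
})
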