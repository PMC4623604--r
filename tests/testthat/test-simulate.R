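test_that("titration simulation honours the zero-ligand and noiseless limits", {
  spec <- titration_sim_spec(noise_sd_h_hz = 0, noise_sd_n_hz = 0, seed = 3)
  s <- simulate_titration(spec)
  # ratio 0: observed displacement from the free position is exactly zero
  first <- dplyr::filter(s, point == 1)
  expect_true(all(first$shift_hz == 0))
  # ratio 30, kd 2.2 mM, P 0.1 mM: displacement ~ 0.572 * delta_max
  truth <- attr(s, "truth")$residues
  endpoint <- dplyr::filter(s, point == max(point), dim == "H") %>%
    dplyr::left_join(truth, by = "residue")
  f_end <- oracle_fraction_bound(0.1, 3.0, 2.2)
  expect_equal(endpoint$shift_hz, f_end * endpoint$delta_max_h_hz,
               tolerance = 1e-7)
  # reported position uncertainty is linewidth / snr
  expect_equal(unique(dplyr::filter(s, dim == "H")$sigma_hz),
               spec$linewidth_h_hz / spec$snr)
})

test_that("titration simulation is bit-reproducible under a fixed seed", {
  a <- simulate_titration(titration_sim_spec(seed = 99))
  b <- simulate_titration(titration_sim_spec(seed = 99))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_titration(titration_sim_spec(seed = 100))
  expect_false(identical(a$shift_hz, c$shift_hz))
})

test_that("titration spec validation rejects non-physical inputs", {
  expect_error(titration_sim_spec(protein_total_uM = -1), "protein_total")
  expect_error(titration_sim_spec(kd_true_mM = 0), "kd_true")
  expect_error(titration_sim_spec(molar_ratios = c(3, 1)), "non-decreasing")
  expect_error(titration_sim_spec(molar_ratios = c(-1, 0)), "non-negative")
  expect_error(titration_sim_spec(noise_sd_h_hz = -0.1), "noise_sd_h_hz")
})

test_that("noiseless simulation round-trips through the global fit to <1% error", {
  for (kd in c(2.2, 4.8)) {
    s <- simulate_titration(titration_sim_spec(
      kd_true_mM = kd, noise_sd_h_hz = 0, noise_sd_n_hz = 0, seed = 1
    ))
    fit <- suppressWarnings(fit_global_kd(s))
    expect_lt(abs(fit$kd_uM - kd * 1000) / (kd * 1000), 0.01)
    # amplitudes recovered too
    truth <- attr(s, "truth")$residues
    dm <- dplyr::filter(fit$delta_max, dim == "H") %>%
      dplyr::left_join(truth, by = "residue")
    expect_lt(max(abs(dm$delta_max_hz - dm$delta_max_h_hz)), 0.5)
  }
})

test_that("two-state trajectory generator obeys its degenerate limits", {
  pairs0 <- tibble::tibble(
    pair = "A_B", mean_compact_A = 10, sd_compact_A = 0,
    mean_extended_A = 30, sd_extended_A = 0
  )
  s <- simulate_two_state_trajectory(two_state_spec(
    pairs = pairs0, dwell_frames = 3, n_frames = 500, seed = 5
  ))
  expect_setequal(unique(s$d_A_B), c(10, 30))
  # infinite dwell pins the chain; sample mean obeys the law of large numbers
  pairs1 <- tibble::tibble(
    pair = "A_B", mean_compact_A = 16.5, sd_compact_A = 2.3,
    mean_extended_A = 99, sd_extended_A = 1
  )
  s1 <- simulate_two_state_trajectory(two_state_spec(
    pairs = pairs1, dwell_frames = Inf, init_state = "compact",
    n_frames = 20000, seed = 6
  ))
  expect_true(all(s1$state_true == "compact"))
  expect_lt(abs(mean(s1$d_A_B) - 16.5), 3 * 2.3 / sqrt(20000))
})

test_that("a 200,000-frame trajectory at 2 ps spans 400 ns", {
  s <- simulate_two_state_trajectory(two_state_spec(n_frames = 200000, seed = 1))
  expect_equal(attr(s, "span_ns"), 400)
  expect_equal(nrow(s), 200000)
})

test_that("seeded two-state runs are reproducible", {
  a <- simulate_two_state_trajectory(two_state_spec(n_frames = 2000, seed = 7))
  b <- simulate_two_state_trajectory(two_state_spec(n_frames = 2000, seed = 7))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("library generator emits requested multiplicities, decoys and truth", {
  spec <- library_sim_spec(
    scaffolds = c(A = "c1ccc2ncccc2c1", B = "c1ccc2[nH]ccc2c1"),
    substituents = c("C", "CC", "OC"),
    multiplicity = c(A = 8, B = 7),
    decoy_fraction = 0.2, seed = 4
  )
  lib <- simulate_library(spec)
  counts <- table(lib$compounds$scaffold, useNA = "ifany")
  expect_equal(unname(counts[["A"]]), 8)
  expect_equal(unname(counts[["B"]]), 7)
  # decoy count: 0.2/(1-0.2) * 15 members = 3.75 -> 4 decoys
  expect_equal(sum(lib$compounds$is_decoy), round(0.25 * 15))
  # frequency ground truth: A's members pass (>= 8), B's fail
  expect_true(all(lib$compounds$truth_freq_pass[lib$compounds$scaffold %in% "A"]))
  expect_false(any(lib$compounds$truth_freq_pass[lib$compounds$scaffold %in% "B"]))
  # decoy fraction 0.2 of the emitted library, exactly
  expect_equal(mean(lib$compounds$is_decoy), 4 / 19, tolerance = 0.02)
})

test_that("library generator with no substituents emits bare scaffolds", {
  lib <- simulate_library(library_sim_spec(
    scaffolds = c(A = "c1ccc2ncccc2c1"),
    substituents = character(0),
    multiplicity = c(A = 3), seed = 2
  ))
  expect_equal(unique(lib$compounds$smiles), "c1ccc2ncccc2c1")
  expect_equal(nrow(lib$compounds), 3)
})

test_that("library generator names unparseable scaffold inputs", {
  expect_error(
    simulate_library(library_sim_spec(
      scaffolds = c(bad = "C1CC("), multiplicity = c(bad = 2), seed = 1
    )),
    "bad"
  )
})

test_that("assay generators are seeded and recover their targets noiselessly", {
  a1 <- simulate_anisotropy(seed = 12)
  a2 <- simulate_anisotropy(seed = 12)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  d1 <- simulate_dose_response(conc = c(1, 3, 10, 30, 100, 300),
                               ic50_true = 30, seed = 8)
  d2 <- simulate_dose_response(conc = c(1, 3, 10, 30, 100, 300),
                               ic50_true = 30, seed = 8)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # noiseless curves sit exactly on the model
  a0 <- simulate_anisotropy(noise_frac = 0, seed = 1)
  tr <- attr(a0, "truth")
  expect_equal(a0$response,
               tr$r_free + (tr$r_bound - tr$r_free) *
                 fraction_bound(20, a0$conc, tr$kd_true),
               tolerance = 1e-12)
})
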