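test_that("identical peak lists give zero perturbations and no flags", {
  ref <- make_peak_list(c(8.1, 8.2, 8.3, 8.4, 8.5))
  prof <- flag_significant(compute_csp(ref, ref))
  expect_true(all(prof$dd_h_hz == 0))
  expect_true(all(prof$dd_n_hz == 0))
  expect_false(any(prof$sig_h | prof$sig_n))
})

test_that("ppm differences convert to Hz at the nucleus frequency", {
  ref <- make_peak_list(rep(8, 4))
  pert <- make_peak_list(rep(8, 4) + c(0.01, 0, 0, 0))
  prof <- compute_csp(ref, pert)
  expect_equal(prof$dd_h_hz[1], 8.0)         # 0.01 ppm at 800 MHz
  # 15N dimension converts at the 15N Larmor frequency
  pertN <- make_peak_list(rep(8, 4), dn_ppm = c(110.1, 110, 110, 110))
  profN <- compute_csp(ref, pertN)
  expect_equal(profN$dd_n_hz[1], 0.1 * 800 * 0.10136767, tolerance = 1e-6)
})

test_that("residues present in only one list are omitted with a message", {
  ref <- make_peak_list(c(8.1, 8.2, 8.3), residues = c("1", "2", "3"))
  pert <- make_peak_list(c(8.1, 8.2), residues = c("1", "2"))
  expect_message(prof <- compute_csp(ref, pert), "omitted")
  expect_setequal(prof$residue, c("1", "2"))
  expect_equal(attr(prof, "dropped"), "3")
})

test_that("field-strength mismatch is an error", {
  ref <- make_peak_list(c(8, 8, 8), field_MHz = 800)
  pert <- make_peak_list(c(8, 8, 8), field_MHz = 600)
  expect_error(compute_csp(ref, pert), "field-strength mismatch")
})

test_that("the dual significance criterion reproduces hand-computed thresholds", {
  ref <- make_peak_list(rep(8, 5))
  # dd_H = {2, 2, 2, 2, 10} Hz: mean 3.6, sample SD ~3.58, threshold ~10.76
  pert <- make_peak_list(8 + c(2, 2, 2, 2, 10) / 800)
  prof <- flag_significant(compute_csp(ref, pert), resolution_h_hz = 2.4)
  st <- attr(prof, "csp_stats")
  h <- st[st$dim == "H", ]
  expect_equal(h$mean_hz, 3.6, tolerance = 1e-6)
  expect_equal(h$sigma_hz, sd(c(2, 2, 2, 2, 10)), tolerance = 1e-6)
  expect_equal(h$threshold_hz, 10.7554, tolerance = 1e-3)
  expect_equal(sum(prof$sig_h), 0)
  # dd_H = {1 x 9, 12}: threshold ~9.06, only the 12 Hz residue flagged
  ref10 <- make_peak_list(rep(8, 10))
  pert10 <- make_peak_list(8 + c(rep(1, 9), 12) / 800)
  prof10 <- flag_significant(compute_csp(ref10, pert10), resolution_h_hz = 2.4)
  expect_equal(which(prof10$sig_h), 10)
  expect_equal(attr(prof10, "csp_stats")$threshold_hz[1], 9.0573, tolerance = 1e-3)
})

test_that("uniform perturbations never self-flag (sigma = 0 degenerate case)", {
  ref <- make_peak_list(rep(8, 6))
  pert <- make_peak_list(rep(8 + 5 / 800, 6))
  prof <- flag_significant(compute_csp(ref, pert))
  expect_false(any(prof$sig_h))
})

test_that("significance needs at least three residues", {
  ref <- make_peak_list(c(8, 8))
  pert <- make_peak_list(c(8.1, 8.0))
  expect_error(flag_significant(compute_csp(ref, pert)), "at least 3")
})

test_that("perturbation magnitude is symmetric in the argument order", {
  withr::with_seed(31, {
    ref <- make_peak_list(8 + runif(8, -0.2, 0.2), dn_ppm = 110 + runif(8, -1, 1))
    pert <- make_peak_list(8 + runif(8, -0.2, 0.2), dn_ppm = 110 + runif(8, -1, 1))
  })
  a <- compute_csp(ref, pert)
  b <- compute_csp(pert, ref)
  expect_equal(a$dd_h_hz, b$dd_h_hz)
  expect_equal(a$dd_n_hz, b$dd_n_hz)
})

test_that("raising the resolution floor never enlarges the flagged set", {
  withr::with_seed(32, {
    dd <- abs(rnorm(30, 2, 4))
  })
  ref <- make_peak_list(rep(8, 30))
  pert <- make_peak_list(8 + dd / 800)
  prof <- compute_csp(ref, pert)
  floors <- c(0, 1, 2.4, 5, 10, 20)
  sets <- lapply(floors, function(fl) {
    which(flag_significant(prof, resolution_h_hz = fl)$sig_h)
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("injected perturbations above the threshold margin are exactly recovered", {
  # 40 quiet residues plus 5 injected large shifts: flagged set == injected set
  withr::with_seed(33, {
    base <- abs(rnorm(45, 1, 0.5))
  })
  injected <- c(5, 15, 25, 35, 45)
  dd <- base
  dd[injected] <- 60 + 5 * seq_along(injected)
  ref <- make_peak_list(rep(8, 45))
  pert <- make_peak_list(8 + dd / 800)
  prof <- flag_significant(compute_csp(ref, pert))
  expect_equal(which(prof$sig_h), injected)
})

test_that("binding patterns classify into the study's groups", {
  expect_equal(classify_binding_pattern(make_flagged_profile(c(87, 88, 89)))$class,
               "group1")
  expect_equal(classify_binding_pattern(make_flagged_profile(c(60, 61, 76, 77, 88)))$class,
               "group2")
  # no flags -> nonbinder
  empty <- make_flagged_profile(c(87))
  empty$sig_h <- FALSE
  expect_equal(classify_binding_pattern(empty)$class, "nonbinder")
  # flags outside the mapped sub-regions -> ambiguous
  expect_equal(classify_binding_pattern(make_flagged_profile(c(88, 30)))$class,
               "ambiguous")
  # tryptophan regions without the aromatic cluster -> ambiguous
  expect_equal(classify_binding_pattern(make_flagged_profile(c(60, 76)))$class,
               "ambiguous")
  # side-chain rows count toward their parent residue
  expect_equal(classify_binding_pattern(make_flagged_profile(c("s-60", "88")))$class,
               "group2")
})

test_that("classification ignores residues with sub-floor perturbations", {
  dd <- c(rep(1, 40), 60, 65, 70)
  residues <- c(as.character(20:59), "87", "88", "89")
  ref <- make_peak_list(rep(8, 43), residues = residues)
  pert <- make_peak_list(8 + dd / 800, residues = residues)
  full <- flag_significant(compute_csp(ref, pert))
  cls_full <- classify_binding_pattern(full)$class
  # dropping sub-floor rows from the flagged profile changes nothing:
  # classification depends only on the flags, which sub-floor residues
  # can never carry
  reduced <- full[full$dd_h_hz > 2.4, ]
  class(reduced) <- class(full)
  cls_red <- classify_binding_pattern(reduced)$class
  expect_equal(cls_full, cls_red)
  expect_equal(cls_full, "group1")
})

test_that("peak lists round-trip through the TSV format", {
  pl <- make_peak_list(c(8.1, 8.25, 10.1), residues = c("60", "61", "s-60"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_list(pl, path)
  back <- read_peak_list(path)
  expect_equal(attr(back, "field_MHz"), 800)
  expect_equal(as.data.frame(back), as.data.frame(pl))
})

test_that("combined-shift mode is available but off the default path", {
  ref <- make_peak_list(c(8, 8, 8))
  pert <- make_peak_list(c(8.01, 8, 8), dn_ppm = c(110.1, 110, 110))
  prof <- combined_csp(compute_csp(ref, pert))
  expect_equal(prof$dd_combined_ppm[1],
               sqrt((0.01^2 + (0.14 * 0.1)^2) / 2), tolerance = 1e-9)
})
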