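test_that("distances extracted from a multi-model PDB are Euclidean", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(list(
    list(W60 = c(0, 0, 0), W76 = c(3, 4, 0), Y88 = c(0, 0, 10)),
    list(W60 = c(1, 1, 1), W76 = c(1, 1, 1), Y88 = c(1, 1, 26))
  ), path)
  expect_warning(s <- extract_distances(path), "degenerate")
  expect_equal(s$d_W60_W76, c(5, 0))        # 3-4-5 triangle; coincident atoms
  expect_equal(s$d_W60_Y88, c(10, 25))
  expect_equal(s$time_ps, c(0, 2))
})

test_that("distances are invariant under rigid rotation and translation", {
  withr::with_seed(41, {
    frames <- lapply(1:5, function(i) {
      list(W60 = rnorm(3, 0, 5), W76 = rnorm(3, 0, 5), Y88 = rnorm(3, 0, 5))
    })
    moved <- lapply(frames, function(fr) {
      R <- random_rotation(); t <- rnorm(3, 0, 20)
      lapply(fr, function(x) as.numeric(R %*% x + t))
    })
  })
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(frames, p1); write_test_pdb(moved, p2)
  a <- extract_distances(p1); b <- extract_distances(p2)
  for (col in c("d_W60_W76", "d_W60_Y88", "d_W76_Y88")) {
    expect_equal(a[[col]], b[[col]], tolerance = 1e-3)
  }
})

test_that("missing atoms are reported by residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_test_pdb(list(list(W60 = c(0, 0, 0), W76 = c(1, 0, 0))), path)
  expect_error(suppressWarnings(extract_distances(path)), "Y88")
})

test_that("window averages equal brute-force block means", {
  s <- simulate_two_state_trajectory(two_state_spec(n_frames = 1050, seed = 3))
  expect_message(avg <- window_average(s, window_ns = 1), "partial")
  # 1 ns at 2 ps = 500 frames per block; naive loop oracle
  for (col in c("d_W60_W76", "d_W60_Y88")) {
    naive <- c(mean(s[[col]][1:500]), mean(s[[col]][501:1000]),
               mean(s[[col]][1001:1050]))
    expect_equal(avg[[col]], naive)
  }
  expect_equal(avg$partial, c(FALSE, FALSE, TRUE))
  # constant series averages to itself; alternating pairs average to midpoints
  const <- s %>% dplyr::mutate(d_W60_W76 = 7)
  attr(const, "frame_ps") <- 2
  expect_equal(unique(suppressMessages(window_average(const, 1))$d_W60_W76), 7)
  alt <- tibble::tibble(frame = 1:10, time_ps = (0:9) * 2,
                        d_A_B = rep(c(10, 20), 5))
  expect_equal(unique(window_average(alt, window_ns = 0.004)$d_A_B), 15)
})

test_that("frame classification applies the strict cutoff rules", {
  base <- tibble::tibble(
    frame = 1:4, time_ps = (0:3) * 2,
    d_W60_W76 = c(15, 15, 15, 15),
    d_W60_Y88 = c(15, 25, 20, 25),
    d_W76_Y88 = c(25, 25, 20, 19)
  )
  cfg <- state_config()
  out <- classify_frames(base, cfg)
  # hub rule: Y88 within 20 of either W; exactly 20 is extended (strict)
  expect_equal(out$state, c("compact", "extended", "extended", "compact"))
  occ <- state_occupancy(out)
  expect_equal(sum(occ), 1)
  expect_equal(unname(occ["compact"]), 0.5)
  # literal any-pair rule: W60-W76 at 15 makes every frame compact
  out_any <- classify_frames(base, state_config(rule = "any"))
  expect_true(all(out_any$state == "compact"))
})

test_that("raising the cutoff never decreases compact occupancy", {
  s <- simulate_two_state_trajectory(two_state_spec(n_frames = 5000, seed = 12))
  occs <- sapply(c(10, 15, 20, 25, 30), function(cut) {
    state_occupancy(classify_frames(s, state_config(cutoff_A = cut)))["compact"]
  })
  expect_true(all(diff(occs) >= 0))
})

test_that("well-separated states are recovered from the trajectory labels", {
  # hub-pair state means 4+ pooled SDs apart straddling the 20 A cutoff
  pairs <- tibble::tibble(
    pair = c("W60_W76", "W60_Y88", "W76_Y88"),
    mean_compact_A = c(16.5, 14, 14), sd_compact_A = c(2.3, 1.4, 1.4),
    mean_extended_A = c(16.5, 26, 26), sd_extended_A = c(2.3, 1.4, 1.4)
  )
  s <- simulate_two_state_trajectory(two_state_spec(
    pairs = pairs, dwell_frames = 500, n_frames = 20000, seed = 8
  ))
  out <- classify_frames(s)
  expect_gt(mean(out$state == out$state_true), 0.95)
})

test_that("distance statistics summarise moments, histograms and states", {
  s <- simulate_two_state_trajectory(two_state_spec(n_frames = 20000, seed = 21))
  st <- distance_statistics(s, config = state_config())
  # W60-W76 is single-state by construction: sample mean near 16.5
  w <- st$summary[st$summary$pair == "W60_W76", ]
  expect_lt(abs(w$mean_A - 16.5), 3 * 2.3 / sqrt(20000))
  # histogram counts conserve frames
  counts <- tapply(st$histogram$count, st$histogram$pair, sum)
  expect_true(all(counts == 20000))
  # zero-SD single state collapses to SD 0
  flatpairs <- tibble::tibble(pair = "A_B", mean_compact_A = 10, sd_compact_A = 0,
                              mean_extended_A = 10, sd_extended_A = 0)
  sf <- simulate_two_state_trajectory(two_state_spec(pairs = flatpairs,
                                                     n_frames = 100, seed = 1))
  stf <- distance_statistics(sf)
  expect_equal(stf$summary$sd_A, 0)
  # per-state summary carries occupancies summing to 1 per pair
  by_state <- st$by_state[st$by_state$pair == "W60_Y88", ]
  expect_equal(sum(by_state$occupancy), 1, tolerance = 1e-12)
})

test_that("contact co-occurrence matches brute-force counting and correlations", {
  s <- simulate_two_state_trajectory(two_state_spec(n_frames = 10000, seed = 31))
  co <- contact_cooccurrence(s, cutoff_A = 20)
  # brute force oracle for one pair-of-pairs
  both <- mean(s$d_W60_W76 < 20 & s$d_W60_Y88 < 20)
  expect_equal(co$co_fraction[co$pair_a == "W60_W76" & co$pair_b == "W60_Y88"], both)
  expect_equal(co$correlation[co$pair_a == "W60_W76" & co$pair_b == "W60_Y88"],
               cor(s$d_W60_W76, s$d_W60_Y88))
  # identical traces correlate at exactly 1
  dup <- tibble::tibble(frame = 1:100, time_ps = (0:99) * 2,
                        d_A_B = rnorm(100, 20, 3))
  dup$d_C_D <- dup$d_A_B
  expect_equal(contact_cooccurrence(dup)$correlation, 1)
  # constant trace: correlation undefined, flagged
  dup$d_C_D <- 15
  co2 <- contact_cooccurrence(dup)
  expect_true(is.na(co2$correlation))
  expect_match(co2$note, "constant")
})

test_that("anti-phase contacts give a near-zero triple-contact fraction", {
  # Y88 near W60 exactly when far from W76 and vice versa
  n <- 4000
  withr::with_seed(51, phase <- rep(c(TRUE, FALSE), n / 2))
  s <- tibble::tibble(
    frame = 1:n, time_ps = (seq_len(n) - 1) * 2,
    d_W60_W76 = 16.5,
    d_W60_Y88 = ifelse(phase, 14, 26),
    d_W76_Y88 = ifelse(phase, 26, 14)
  )
  co <- contact_cooccurrence(s, cutoff_A = 20)
  expect_equal(attr(co, "all_contact_fraction"), 0)
  y_pair <- co[co$pair_a == "W60_Y88" & co$pair_b == "W76_Y88", ]
  expect_equal(y_pair$co_fraction, 0)
})

test_that("independent traces co-occur at the product of marginals", {
  withr::with_seed(61, {
    s <- tibble::tibble(
      frame = 1:20000, time_ps = (0:19999) * 2,
      d_A_B = rnorm(20000, 20, 4),
      d_C_D = rnorm(20000, 21, 5)
    )
  })
  co <- contact_cooccurrence(s, cutoff_A = 20)
  expect_equal(co$co_fraction, co$independent_fraction, tolerance = 0.02)
})

test_that("window-averaging then classifying differs from frame-wise classification", {
  # documented non-property: the order of operations matters because block
  # means smooth over state switches
  s <- simulate_two_state_trajectory(two_state_spec(dwell_frames = 100,
                                                    n_frames = 20000, seed = 71))
  framewise <- state_occupancy(classify_frames(s))
  avg <- suppressMessages(window_average(s, window_ns = 1))
  avg_series <- dplyr::mutate(avg, frame = dplyr::row_number())
  attr(avg_series, "frame_ps") <- 1000
  blockwise <- state_occupancy(classify_frames(avg_series))
  expect_false(isTRUE(all.equal(unname(framewise["compact"]),
                                unname(blockwise["compact"]),
                                tolerance = 1e-3)))
})

test_that("distance tables round-trip through CSV", {
  s <- simulate_two_state_trajectory(two_state_spec(n_frames = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(as.data.frame(s), time_ps,
                                 dplyr::starts_with("d_")), path)
  back <- read_distance_table(path)
  expect_equal(back$d_W60_W76, s$d_W60_W76)
  expect_equal(attr(back, "frame_ps"), 2)
})
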