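test_that("sanitisation separates valid, isotope, inorganic and invalid entries", {
  out <- sanitize_library(c(
    benzene = "c1ccccc1",
    iso = "[13CH4]",
    iron = "[Fe+2]",
    broken = "C1CC("
  ))
  expect_equal(out$records$id, "benzene")
  expect_equal(
    unname(out$rejects$reason[match(c("iso", "iron", "broken"), out$rejects$id)]),
    c("isotope", "inorganic", "invalid")
  )
  # empty input is empty output, not an error
  empty <- sanitize_library(character(0))
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$rejects), 0)
})

test_that("computed properties match hand-derived benzene values", {
  rec <- sanitize_library(c(benzene = "c1ccccc1"))$records
  expect_equal(rec$mw, 78.11, tolerance = 1e-3)
  expect_equal(rec$heavy_atoms, 6L)
  expect_equal(rec$hbd, 0)
  expect_equal(rec$hba, 0)
  expect_equal(rec$ring_count, 1L)
  expect_equal(rec$rotatable_bonds, 0L)
})

test_that("Murcko scaffolds follow the ring-and-linker rule with alpha atoms", {
  # all-ring molecule is its own scaffold
  bip <- murcko_scaffold("c1ccc(-c2ccccc2)cc1")
  ref <- sanitize_library(c(x = "c1ccc(-c2ccccc2)cc1"))$records$cansmi
  expect_equal(bip$scaffold_smiles, ref)
  expect_equal(bip$ring_count, 2L)
  # ethylbenzene with alpha atoms keeps the attached carbon (toluene shape)
  tol <- sanitize_library(c(x = "Cc1ccccc1"))$records$cansmi
  expect_equal(murcko_scaffold("CCc1ccccc1")$scaffold_smiles, tol)
  # without alpha atoms the bare ring remains
  benz <- sanitize_library(c(x = "c1ccccc1"))$records$cansmi
  expect_equal(murcko_scaffold("CCc1ccccc1", keep_alpha = FALSE)$scaffold_smiles,
               benz)
  # acyclic molecules have an empty scaffold
  hex <- murcko_scaffold("CCCCCC")
  expect_equal(hex$scaffold_smiles, "")
  expect_equal(hex$ring_count, 0L)
})

test_that("the no-alpha scaffold is a substructure of the alpha scaffold", {
  smiles <- c("CCc1ccccc1", "OCc1ccc2ncccc2c1", "CC(=O)Nc1ccc(O)cc1",
              "c1ccc2[nH]ccc2c1", "OCCc1cncnc1")
  for (s in smiles) {
    with_alpha <- murcko_scaffold(s, keep_alpha = TRUE)
    without <- murcko_scaffold(s, keep_alpha = FALSE)
    expect_lte(without$heavy_atoms, with_alpha$heavy_atoms)
    expect_equal(without$ring_count, with_alpha$ring_count)
  }
})

test_that("the scaffold filter cascade applies every printed rule with reasons", {
  scaffolds <- tibble::tibble(
    scaffold_smiles = c("Cc1ccc2c(c1)nccc2",  # 2-ring, fine
                        "Cc1ccccc1",          # single ring, 1 substitution
                        "c1ccncc1"),          # 9-heavy fails size? no: 6
    members = list("a", "b", "c"), n_members = c(1, 1, 1),
    heavy_atoms = c(11L, 7L, 9L),
    rotatable_bonds = c(0L, 0L, 0L),
    ring_count = c(2L, 1L, 1L),
    ring_substitutions = c(1L, 1L, 0L)
  )
  freq <- tibble::tibble(
    scaffold_smiles = c("c1ccc2c(c1)nccc2", "c1ccccc1"),
    count = c(8L, 20L)
  )
  out <- suppressMessages(apply_scaffold_filters(scaffolds, filter_config(), freq))
  # boundary: frequency exactly 8 passes
  expect_true(out$pass[1])
  expect_equal(out$fail_reasons[1], "")
  # single-ring with only one substitution fails the substitution rule
  expect_false(out$pass[2])
  expect_match(out$fail_reasons[2], "substitution")
  expect_match(out$fail_reasons[2], "heavy")
  # heavy_atoms = 9 fails the size rule; absent from frequency table -> 0
  expect_false(out$pass[3])
  expect_match(out$fail_reasons[3], "heavy")
  expect_match(out$fail_reasons[3], "frequency")
  expect_equal(out$hts_frequency[3], 0)
})

test_that("reactive substructures are flagged by the SMARTS screen", {
  scaffolds <- tibble::tibble(
    scaffold_smiles = c("O=CCc1ccc2c(c1)nccc2",   # aldehyde
                        "Cc1ccc2c(c1)nccc2"),     # clean
    members = list("a", "b"), n_members = c(1, 1),
    heavy_atoms = c(13L, 11L), rotatable_bonds = c(1L, 0L),
    ring_count = c(2L, 2L), ring_substitutions = c(1L, 1L)
  )
  freq <- tibble::tibble(scaffold_smiles = "c1ccc2c(c1)nccc2", count = 10L)
  out <- apply_scaffold_filters(scaffolds, filter_config(), freq)
  expect_equal(out$n_reactive, c(1L, 0L))
  expect_false(out$pass[1])
  expect_match(out$fail_reasons[1], "reactive")
  expect_true(out$pass[2])
})

test_that("Rule-of-Three boundaries are exactly as printed", {
  recs <- tibble::tibble(
    id = c("edge", "mw300", "hba4", "na"),
    mw = c(299.9, 300.0, 250, NA),
    hbd = c(3, 0, 0, 1), hba = c(3, 0, 4, 1), clogp = c(3.0, 1, 1, 1)
  )
  out <- check_ro3(recs)
  expect_equal(out$ro3_pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(out$ro3_fail_reasons[2], "mw")
  expect_match(out$ro3_fail_reasons[3], "hba")
  expect_equal(out$ro3_fail_reasons[4], "uncomputed")
})

test_that("complexity ranking is a stable descending sort with id tie-breaks", {
  recs <- tibble::tibble(
    id = c("a", "c", "b"), smiles = NA_character_, cansmi = "c1ccccc1",
    ring_count = c(1L, 2L, 2L), heavy_atoms = c(10L, 12L, 12L),
    rotatable_bonds = c(0L, 0L, 0L), mw = 100, hbd = 0, hba = 0, clogp = 1,
    psa = 0
  )
  ranked <- rank_by_complexity(recs)
  expect_equal(ranked$id, c("b", "c", "a")) # tie between b and c -> id order
  # a permutation oracle: any input order gives the same output order
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(rank_by_complexity(recs[perm, ])$id, ranked$id)
  }
  single <- rank_by_complexity(recs[1, ])
  expect_equal(single$id, "a")
})

test_that("library profiling reports means and sample SDs", {
  recs <- tibble::tibble(
    id = c("x", "y"), mw = c(200, 300), heavy_atoms = c(14, 20),
    clogp = c(1, 2), psa = c(40, 60), hba = c(2, 3), hbd = c(1, 1)
  )
  prof <- profile_library(recs)
  mw <- prof[prof$property == "mw", ]
  expect_equal(mw$mean, 250)
  expect_equal(mw$sd, sd(c(200, 300)))
  expect_equal(mw$sd, 70.71, tolerance = 1e-3)
  # singleton library: SD 0 with a warning
  expect_warning(p1 <- profile_library(recs[1, ]), "single")
  expect_true(all(p1$sd == 0))
  expect_error(profile_library(recs[0, ]), "empty")
})

test_that("curation verdicts equal the generator's ground truth", {
  lib <- simulate_library(library_sim_spec(decoy_fraction = 0.2, seed = 14))
  cur <- suppressMessages(curate_library(
    dplyr::select(lib$compounds, id, smiles), lib$hts_frequencies
  ))
  # every decoy rejected with the right reason
  truth <- lib$compounds
  rej <- dplyr::left_join(cur$rejects, truth, by = "id")
  expect_setequal(cur$rejects$id, truth$id[truth$is_decoy])
  expect_equal(rej$reason, rej$decoy_type)
  # frequency verdicts match multiplicity ground truth for every member
  chk <- cur$records %>%
    dplyr::left_join(dplyr::select(truth, id, truth_freq_pass), by = "id") %>%
    dplyr::left_join(dplyr::select(cur$scaffolds, scaffold_smiles, pass_frequency),
                     by = "scaffold_smiles")
  expect_equal(chk$pass_frequency, chk$truth_freq_pass)
})

test_that("the curation pipeline is idempotent and order-invariant", {
  lib <- simulate_library(library_sim_spec(seed = 15))
  input <- dplyr::select(lib$compounds, id, smiles)
  cur1 <- suppressMessages(curate_library(input, lib$hts_frequencies))
  # re-run on its own surviving output: verdicts unchanged
  survivors <- dplyr::select(cur1$records, id, smiles)
  cur2 <- suppressMessages(curate_library(survivors, lib$hts_frequencies))
  j <- dplyr::inner_join(
    dplyr::select(cur1$records, id, s1 = selected),
    dplyr::select(cur2$records, id, s2 = selected), by = "id"
  )
  expect_equal(nrow(j), nrow(cur2$records))
  expect_equal(j$s1, j$s2)
  # permuted input gives identical scaffold verdicts and record verdicts
  withr::with_seed(3, perm <- sample(nrow(input)))
  cur3 <- suppressMessages(curate_library(input[perm, ], lib$hts_frequencies))
  a <- dplyr::arrange(dplyr::select(cur1$records, id, selected, scaffold_pass), id)
  b <- dplyr::arrange(dplyr::select(cur3$records, id, selected, scaffold_pass), id)
  expect_equal(a, b)
})

test_that("SMILES files read as one-molecule-per-line with trailing ids", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol", ""), path)
  tbl <- read_smiles_file(path)
  expect_equal(tbl$id, c("benzene", "ethanol"))
  expect_equal(tbl$smiles, c("c1ccccc1", "CCO"))
})
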