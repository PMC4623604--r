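# Fragment-library curation: validity sanitisation, Murcko scaffold
# abstraction with alpha atoms, the scaffold filter cascade (reactive
# substructures, size/flexibility, screening-collection frequency),
# Rule-of-Three checks, complexity ranking and library profiling.

#' Filter configuration for library curation
#'
#' Thresholds default to the selection algorithm's published rules: zero
#' reactive substructures, at most 3 rotatable bonds, at least 10 heavy
#' atoms, at least 1 ring, more than 1 ring substitution for single-ring
#' systems, and a screening-collection frequency of at least 8. Boundary
#' semantics are exactly as printed (strict `< 300` for the Rule-of-Three
#' molecular weight; `<=`/`>=` elsewhere).
#'
#' @param reactive_smarts Tibble with columns `name`, `smarts`, or a path to
#'   a two-column TSV. Default: the REOS-style set shipped with the package
#'   (`system.file("extdata", "reos_smarts.tsv", package = "idpfrag")`);
#'   the published filter sets are cited, not listed, so the patterns are
#'   user-overridable.
#' @param max_rotatable Maximum rotatable bonds on the scaffold.
#' @param min_heavy Minimum heavy atoms on the scaffold.
#' @param min_rings Minimum ring count.
#' @param min_single_ring_subst Single-ring scaffolds need strictly more
#'   than this many ring substitutions (default 1, i.e. `> 1`).
#' @param min_hts_freq Minimum screening-collection frequency.
#' @param ro3_mw,ro3_hbd,ro3_hba,ro3_clogp Rule-of-Three thresholds
#'   (MW strictly below; others at most).
#' @param filter_on `"scaffold"` (default, per the published wording) or
#'   `"parent"`: which structure the rotatable-bond/heavy-atom/ring rules
#'   are evaluated on.
#' @return A `filter_config` list.
#' @export
filter_config <- function(reactive_smarts = NULL,
                          max_rotatable = 3, min_heavy = 10, min_rings = 1,
                          min_single_ring_subst = 1, min_hts_freq = 8,
                          ro3_mw = 300, ro3_hbd = 3, ro3_hba = 3, ro3_clogp = 3,
                          filter_on = c("scaffold", "parent")) {
  filter_on <- match.arg(filter_on)
  if (is.null(reactive_smarts)) {
    reactive_smarts <- system.file("extdata", "reos_smarts.tsv", package = "idpfrag")
  }
  if (is.character(reactive_smarts)) {
    # full-line comments only: '#' is a ring-bond/atom token inside SMARTS
    lines <- readLines(reactive_smarts)
    lines <- lines[!startsWith(trimws(lines), "#")]
    reactive_smarts <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                                       show_col_types = FALSE)
  }
  reactive_smarts <- as_tibble(reactive_smarts)
  if (!all(c("name", "smarts") %in% names(reactive_smarts))) {
    abort("`reactive_smarts` needs columns name and smarts")
  }
  structure(
    list(reactive_smarts = reactive_smarts, max_rotatable = max_rotatable,
         min_heavy = min_heavy, min_rings = min_rings,
         min_single_ring_subst = min_single_ring_subst,
         min_hts_freq = min_hts_freq,
         ro3 = list(mw = ro3_mw, hbd = ro3_hbd, hba = ro3_hba, clogp = ro3_clogp),
         filter_on = filter_on),
    class = "filter_config"
  )
}

#' Sanitise a molecule library
#'
#' Splits raw SMILES entries into valid compound records and rejects. An
#' entry is rejected as `isotope` if it carries an isotope label, as
#' `inorganic` if it contains elements outside the organic whitelist (H, B,
#' C, N, O, F, P, S, Cl, Br, I), and as `invalid` if it does not parse.
#' Valid entries get a full physicochemical record: canonical SMILES, MW,
#' heavy atoms, clogP, topological PSA, H-bond acceptors/donors, rotatable
#' bonds and ring count.
#'
#' @param smiles Character vector of SMILES, a named vector (names become
#'   ids), or a tibble with columns `id`, `smiles`.
#' @param ids Optional explicit ids.
#' @return List with `records` (tibble of valid compounds) and `rejects`
#'   (tibble `id`, `smiles`, `reason`). Empty input gives empty tibbles.
#' @export
sanitize_library <- function(smiles, ids = NULL) {
  if (is.data.frame(smiles)) {
    ids <- smiles$id
    smiles <- smiles$smiles
  }
  if (is.null(ids)) ids <- names(smiles) %||% sprintf("M%04d", seq_along(smiles))
  if (length(smiles) == 0) {
    return(list(records = tibble(), rejects = tibble()))
  }
  verdict <- purrr::map_chr(unname(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return("invalid")
    if (has_isotope(s)) return("isotope")
    els <- smiles_elements(s)
    if (length(els) > 0 && !all(els %in% ORGANIC_ELEMENTS)) return("inorganic")
    if (!smiles_parses(s)) return("invalid")
    "valid"
  })
  rejects <- tibble(id = ids, smiles = smiles, reason = verdict) %>%
    filter(.data$reason != "valid")
  ok <- verdict == "valid"
  records <- if (any(ok)) {
    compound_properties(smiles[ok], ids[ok])
  } else {
    tibble()
  }
  list(records = records, rejects = rejects)
}

#' Physicochemical properties for parseable SMILES
#'
#' @param smiles Parseable SMILES vector.
#' @param ids Ids (same length).
#' @return Tibble: `id`, `smiles`, `cansmi`, `mw`, `heavy_atoms`, `clogp`,
#'   `psa`, `hba`, `hbd`, `rotatable_bonds`, `ring_count`.
#' @export
compound_properties <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- names(smiles) %||% sprintf("M%04d", seq_along(smiles))
  sdfset <- ChemmineR::smiles2sdf(setNames(smiles, ids))
  props <- ChemmineR::propOB(sdfset)
  graph_stats <- purrr::map_dfr(seq_along(sdfset), function(i) {
    g <- mol_graph(sdfset[[i]])
    tibble(
      heavy_atoms = length(g$heavy),
      rotatable_bonds = graph_rotatable_bonds(g),
      ring_count = graph_ring_count(g)
    )
  })
  tibble(
    id = ids, smiles = unname(smiles),
    cansmi = props$cansmi,
    mw = props$MW, clogp = props$logP, psa = props$TPSA,
    hba = props$HBA2, hbd = props$HBD
  ) %>%
    dplyr::bind_cols(graph_stats) %>%
    select("id", "smiles", "cansmi", "mw", "heavy_atoms", "clogp", "psa",
           "hba", "hbd", "rotatable_bonds", "ring_count")
}

#' Murcko scaffold of a molecule
#'
#' Abstracts a molecule to its Murcko framework: ring systems plus the
#' linkers connecting them, obtained by iteratively pruning terminal heavy
#' atoms. With `keep_alpha` (the default) atoms directly bonded to the
#' framework — the alpha atoms — are preserved on the scaffold, matching
#' scaffold generation "with alpha atoms preserved". Scaffolds are
#' canonicalised so identical frameworks merge; acyclic molecules yield the
#' empty scaffold `""`.
#'
#' Scaffold-level descriptors are computed on the scaffold structure:
#' `heavy_atoms`, `rotatable_bonds`, `ring_count`, and `ring_substitutions`
#' (attachment points: bonds from the ring/linker core to atoms outside it,
#' counted on the parent).
#'
#' @param smiles A single SMILES string (or a one-row record with a
#'   `smiles` column).
#' @param keep_alpha Preserve alpha atoms on the scaffold? Default TRUE.
#' @return One-row tibble: `scaffold_smiles`, `heavy_atoms`,
#'   `rotatable_bonds`, `ring_count`, `ring_substitutions`.
#' @examples
#' murcko_scaffold("CCc1ccccc1")$scaffold_smiles # toluene-like: ring + alpha C
#' @export
murcko_scaffold <- function(smiles, keep_alpha = TRUE) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles[[1]]
  assert_flag(keep_alpha, "keep_alpha")
  sdf <- parse_smiles_one(smiles)
  if (is.null(sdf)) abort(sprintf("not parseable SMILES: %s", smiles))
  g <- mol_graph(sdf)
  core <- murcko_core(g)
  if (length(core) == 0) {
    return(tibble(scaffold_smiles = "", heavy_atoms = 0L, rotatable_bonds = 0L,
                  ring_count = 0L, ring_substitutions = 0L))
  }
  alpha <- alpha_atoms(g, core)
  scaffold_atoms <- if (keep_alpha) sort(c(core, alpha)) else sort(core)
  # attachment points: parent bonds from the core out to non-core heavy atoms
  in_core <- seq_along(g$elements) %in% core
  ext_bonds <- sum(xor(in_core[g$bonds[, 1]], in_core[g$bonds[, 2]]) &
                     g$bonds[, 1] %in% g$heavy & g$bonds[, 2] %in% g$heavy)
  tibble(
    scaffold_smiles = subgraph_cansmi(g, scaffold_atoms),
    heavy_atoms = length(scaffold_atoms),
    rotatable_bonds = graph_rotatable_bonds(g, scaffold_atoms),
    ring_count = graph_ring_count(g, scaffold_atoms),
    ring_substitutions = as.integer(ext_bonds)
  )
}

#' Group compound records by their Murcko scaffold
#'
#' @param records Compound records from [sanitize_library()].
#' @param keep_alpha Preserve alpha atoms (see [murcko_scaffold()]).
#' @return A scaffold tibble: `scaffold_smiles`, `members` (list of ids),
#'   `n_members`, plus the scaffold descriptors of [murcko_scaffold()]
#'   (taken from the first member; identical scaffolds share them up to the
#'   attachment-point count, for which the maximum over members is kept).
#' @export
scaffold_table <- function(records, keep_alpha = TRUE) {
  if (nrow(records) == 0) return(tibble())
  per_mol <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    murcko_scaffold(records$smiles[[i]], keep_alpha = keep_alpha) %>%
      mutate(id = records$id[[i]])
  })
  per_mol %>%
    group_by(.data$scaffold_smiles) %>%
    summarise(
      members = list(.data$id),
      n_members = n(),
      heavy_atoms = first(.data$heavy_atoms),
      rotatable_bonds = first(.data$rotatable_bonds),
      ring_count = first(.data$ring_count),
      ring_substitutions = max(.data$ring_substitutions),
      .groups = "drop"
    )
}

#' Apply the scaffold filter cascade
#'
#' A scaffold passes iff it has zero reactive-substructure matches AND at
#' most 3 rotatable bonds AND at least 10 heavy atoms AND at least one ring
#' AND (more than one ring OR more than one ring substitution) AND a
#' screening-collection frequency of at least 8 (all thresholds
#' configurable). Every failure reason is recorded. Scaffolds absent from
#' the frequency table get frequency 0 (and fail that rule) with a message.
#'
#' Frequency-table keys are bare Murcko frameworks (no alpha atoms), since
#' a "molecules containing the scaffold" count is indifferent to the
#' attachment-atom decoration; scaffolds carrying alpha atoms are reduced
#' to their framework for the lookup.
#'
#' @param scaffolds Scaffold tibble from [scaffold_table()].
#' @param config A [filter_config()].
#' @param hts_frequencies Tibble mapping `scaffold_smiles` (bare framework,
#'   canonical) to `count` in the reference screening collection.
#' @return The scaffold tibble with `hts_frequency`, `n_reactive`, logical
#'   per-rule columns (`pass_reactive`, `pass_rotatable`, `pass_heavy`,
#'   `pass_rings`, `pass_substitution`, `pass_frequency`), `pass` and
#'   `fail_reasons`.
#' @export
apply_scaffold_filters <- function(scaffolds, config = filter_config(),
                                   hts_frequencies) {
  if (nrow(scaffolds) == 0) return(scaffolds)
  hts_frequencies <- as_tibble(hts_frequencies)
  if (!all(c("scaffold_smiles", "count") %in% names(hts_frequencies))) {
    abort("`hts_frequencies` needs columns scaffold_smiles and count")
  }
  framework <- purrr::map_chr(scaffolds$scaffold_smiles, function(s) {
    if (!nzchar(s) || is.na(s)) return("")
    murcko_scaffold(s, keep_alpha = FALSE)$scaffold_smiles
  })
  sc <- scaffolds %>%
    mutate(framework_smiles = framework) %>%
    left_join(hts_frequencies %>%
                select(framework_smiles = "scaffold_smiles", "count"),
              by = "framework_smiles") %>%
    rename(hts_frequency = "count")
  if (any(is.na(sc$hts_frequency))) {
    inform(sprintf("%d scaffold(s) absent from the frequency table; frequency set to 0",
                   sum(is.na(sc$hts_frequency))))
    sc$hts_frequency <- sc$hts_frequency %ifna% 0L
  }
  # reactive-substructure matches via OpenBabel SMARTS filters
  key <- sprintf("S%05d", seq_len(nrow(sc)))
  n_reactive <- rep(0L, nrow(sc))
  for (i in seq_len(nrow(config$reactive_smarts))) {
    hit <- obabel_smarts_filter(sc$scaffold_smiles, key,
                                config$reactive_smarts$smarts[[i]])
    n_reactive[key %in% hit] <- n_reactive[key %in% hit] + 1L
  }
  out <- sc %>%
    mutate(
      n_reactive = n_reactive,
      pass_reactive = .data$n_reactive == 0,
      pass_rotatable = .data$rotatable_bonds <= config$max_rotatable,
      pass_heavy = .data$heavy_atoms >= config$min_heavy,
      pass_rings = .data$ring_count >= config$min_rings,
      pass_substitution = .data$ring_count > 1 |
        .data$ring_substitutions > config$min_single_ring_subst,
      pass_frequency = .data$hts_frequency >= config$min_hts_freq,
      pass = .data$pass_reactive & .data$pass_rotatable & .data$pass_heavy &
        .data$pass_rings & .data$pass_substitution & .data$pass_frequency
    )
  rules <- c("reactive", "rotatable", "heavy", "rings", "substitution", "frequency")
  out$fail_reasons <- purrr::pmap_chr(
    out[paste0("pass_", rules)],
    function(...) paste(rules[!c(...)], collapse = ",")
  )
  out
}

#' Rule-of-Three check
#'
#' A fragment passes iff MW strictly below 300 Da, at most 3 H-bond donors,
#' at most 3 H-bond acceptors and clogP at most 3 (thresholds from the
#' config). Records with a missing property fail with reason `uncomputed`.
#'
#' @param records Compound records with `mw`, `hbd`, `hba`, `clogp`.
#' @param config A [filter_config()] (for the thresholds).
#' @return The records with logical `ro3_mw`, `ro3_hbd`, `ro3_hba`,
#'   `ro3_clogp`, `ro3_pass` and `ro3_fail_reasons` columns.
#' @export
check_ro3 <- function(records, config = filter_config()) {
  records <- as_tibble(records)
  needed <- c("mw", "hbd", "hba", "clogp")
  if (!all(needed %in% names(records))) {
    abort(paste0("`records` needs columns: ", paste(needed, collapse = ", ")))
  }
  t <- config$ro3
  out <- records %>%
    mutate(
      ro3_mw = .data$mw < t$mw,
      ro3_hbd = .data$hbd <= t$hbd,
      ro3_hba = .data$hba <= t$hba,
      ro3_clogp = .data$clogp <= t$clogp
    )
  crit <- c("mw", "hbd", "hba", "clogp")
  out$ro3_fail_reasons <- purrr::pmap_chr(
    out[paste0("ro3_", crit)],
    function(...) {
      v <- c(...)
      if (any(is.na(v))) return("uncomputed")
      paste(crit[!v], collapse = ",")
    }
  )
  out %>%
    mutate(ro3_pass = .data$ro3_fail_reasons == "")
}

#' Structural complexity score
#'
#' An additive complexity score used to prioritise candidate fragments for
#' purchase: a weighted sum of ring count, heteroatom count, heavy-atom
#' count and rotatable bonds. The published selection ranked by a cited
#' complexity metric whose exact definition is external; only the ranking
#' behaviour matters downstream, so the scorer is pluggable
#' (see [rank_by_complexity()]) and its weights configurable.
#'
#' @param records Compound records (needs `ring_count`, `heavy_atoms`,
#'   `rotatable_bonds`, `cansmi`).
#' @param w_ring,w_hetero,w_heavy,w_rot Weights.
#' @return Numeric score vector.
#' @export
complexity_score <- function(records, w_ring = 2, w_hetero = 1,
                             w_heavy = 0.1, w_rot = 0.5) {
  hetero <- purrr::map_int(records$cansmi %||% records$smiles, function(s) {
    els <- smiles_elements(s)
    # count heteroatom tokens (upper- and lower-case aromatic forms)
    n <- 0L
    for (e in setdiff(els, c("C", "H"))) {
      n <- n + stringr::str_count(s, paste0("(?i)", e))
    }
    n
  })
  w_ring * records$ring_count + w_hetero * hetero +
    w_heavy * records$heavy_atoms + w_rot * records$rotatable_bonds
}

#' Rank compounds by complexity
#'
#' Stable descending sort by a complexity score, ties broken
#' lexicographically by id for determinism.
#'
#' @param records Compound records.
#' @param score_fn Function records -> numeric score
#'   (default [complexity_score()]).
#' @return The records, ordered, with a `complexity` column.
#' @export
rank_by_complexity <- function(records, score_fn = complexity_score) {
  records <- as_tibble(records)
  if (nrow(records) == 0) return(records)
  records %>%
    mutate(complexity = score_fn(records)) %>%
    arrange(desc(.data$complexity), .data$id)
}

#' Physicochemical profile of a library
#'
#' Mean and sample SD (n-1 denominator) of the standard fragment properties.
#' A single-compound library reports SD 0 with a warning.
#'
#' @param records Compound records (>= 1 row).
#' @return Tibble: `property`, `mean`, `sd`, `n`.
#' @export
profile_library <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("cannot profile an empty library")
  if (nrow(records) == 1) {
    warn("single-compound library: standard deviations reported as 0")
  }
  props <- c("mw", "heavy_atoms", "clogp", "psa", "hba", "hbd")
  purrr::map_dfr(props, function(p) {
    x <- records[[p]]
    tibble(property = p, mean = mean(x, na.rm = TRUE),
           sd = suppressWarnings(sample_sd(x)), n = sum(!is.na(x)))
  })
}

#' End-to-end library curation
#'
#' Runs the full selection pipeline: sanitise, abstract to scaffolds, apply
#' the scaffold filter cascade against a screening-collection frequency
#' table, check the Rule of Three on the parent compounds, and rank the
#' survivors by complexity.
#'
#' @param smiles SMILES input (see [sanitize_library()]).
#' @param hts_frequencies Frequency table (`scaffold_smiles`, `count`).
#' @param config A [filter_config()].
#' @param keep_alpha Preserve alpha atoms on scaffolds.
#' @return List: `records` (per-compound verdicts incl. `scaffold_smiles`,
#'   `scaffold_pass`, `ro3_pass`, `selected`, ranked by complexity),
#'   `scaffolds` (filter table), `rejects`.
#' @export
curate_library <- function(smiles, hts_frequencies, config = filter_config(),
                           keep_alpha = TRUE) {
  san <- sanitize_library(smiles)
  if (nrow(san$records) == 0) {
    return(list(records = tibble(), scaffolds = tibble(), rejects = san$rejects))
  }
  per_mol <- purrr::map_dfr(seq_len(nrow(san$records)), function(i) {
    murcko_scaffold(san$records$smiles[[i]], keep_alpha = keep_alpha) %>%
      select(scaffold_smiles = "scaffold_smiles")
  })
  records <- dplyr::bind_cols(san$records, per_mol)
  scaffolds <- scaffold_table(san$records, keep_alpha = keep_alpha)
  scaffolds <- apply_scaffold_filters(scaffolds, config, hts_frequencies)
  records <- records %>%
    left_join(scaffolds %>% select("scaffold_smiles", scaffold_pass = "pass"),
              by = "scaffold_smiles") %>%
    check_ro3(config) %>%
    mutate(selected = .data$scaffold_pass & .data$ro3_pass) %>%
    rank_by_complexity()
  list(records = records, scaffolds = scaffolds, rejects = san$rejects)
}

#' Read a SMILES file (one molecule per line, id after whitespace)
#'
#' @param path File path.
#' @return Tibble `id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(trimws(lines), "\\s+", 2)
  ids <- ifelse(nzchar(parts[, 2]), parts[, 2], sprintf("M%04d", seq_along(lines)))
  tibble(id = ids, smiles = parts[, 1])
}
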