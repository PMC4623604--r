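# Synthetic-data generators. Each generator consumes a validated spec object
# and is bit-reproducible under its seed; ground truth travels along as
# attributes so downstream recovery tests can score themselves.

#' Specification for a synthetic fast-exchange titration
#'
#' Defines the conditions of a simulated 2D 1H-15N titration of a small
#' molecule into an isotopically labelled disordered protein domain under
#' fast exchange: constant protein total, a ladder of ligand:protein molar
#' ratios, a ground-truth dissociation constant, per-residue maximum shift
#' changes, and additive Gaussian position noise per dimension.
#'
#' Defaults reproduce the screening study's titration conditions: 100 uM
#' protein, the sixteen-point ratio ladder 1:0, 1:0.1, 1:1.5, ... 1:30, and
#' position noise equal to the digital resolutions of the 800 MHz in-phase
#' HSQC experiments (2.4 Hz in 1H, 1.7 Hz in 15N).
#'
#' @param protein_total_uM Protein total concentration (uM), constant across
#'   the ladder.
#' @param molar_ratios Ligand:protein molar ratios, non-negative and
#'   non-decreasing; the first point should be 0 (ligand-free reference).
#' @param kd_true_mM Ground-truth dissociation constant (mM).
#' @param residues Tibble with columns `residue`, `delta_max_h_hz`,
#'   `delta_max_n_hz`, `dh_free_ppm`, `dn_free_ppm`. Default:
#'   [default_titration_residues()].
#' @param noise_sd_h_hz,noise_sd_n_hz Gaussian SD of peak-position noise per
#'   dimension (Hz, >= 0).
#' @param linewidth_h_hz,linewidth_n_hz Peak line widths (Hz) used to report
#'   position uncertainties.
#' @param snr Signal-to-noise ratio; the reported per-point position
#'   uncertainty is linewidth / snr.
#' @param field_MHz Spectrometer 1H frequency (MHz).
#' @param seed RNG seed (mandatory; simulation is bit-reproducible).
#' @return A `titration_sim_spec` list.
#' @export
titration_sim_spec <- function(protein_total_uM = 100,
                               molar_ratios = c(0, 0.1, 1.5, 3, 4.5, 6, 7.5, 9,
                                                10.5, 12, 15, 18, 21, 24, 27, 30),
                               kd_true_mM = 2.2,
                               residues = default_titration_residues(),
                               noise_sd_h_hz = 2.4, noise_sd_n_hz = 1.7,
                               linewidth_h_hz = 20, linewidth_n_hz = 15,
                               snr = 50, field_MHz = 800, seed = 1L) {
  assert_number(protein_total_uM, "protein_total_uM", lower = 0, strict = TRUE)
  assert_number(kd_true_mM, "kd_true_mM", lower = 0, strict = TRUE)
  assert_number(noise_sd_h_hz, "noise_sd_h_hz", lower = 0)
  assert_number(noise_sd_n_hz, "noise_sd_n_hz", lower = 0)
  assert_number(linewidth_h_hz, "linewidth_h_hz", lower = 0, strict = TRUE)
  assert_number(linewidth_n_hz, "linewidth_n_hz", lower = 0, strict = TRUE)
  assert_number(snr, "snr", lower = 0, strict = TRUE)
  assert_number(field_MHz, "field_MHz", lower = 0, strict = TRUE)
  if (!is.numeric(molar_ratios) || length(molar_ratios) < 2) {
    abort("`molar_ratios` must be a numeric ladder with at least two points")
  }
  if (any(molar_ratios < 0)) abort("`molar_ratios` must be non-negative")
  if (is.unsorted(molar_ratios)) abort("`molar_ratios` must be non-decreasing")
  residues <- as_tibble(residues)
  needed <- c("residue", "delta_max_h_hz", "delta_max_n_hz",
              "dh_free_ppm", "dn_free_ppm")
  if (!all(needed %in% names(residues))) {
    abort(paste0("`residues` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(residues$residue)) abort("residue labels must be unique")
  structure(
    list(
      protein_total_uM = protein_total_uM, molar_ratios = molar_ratios,
      kd_true_mM = kd_true_mM, residues = residues,
      noise_sd_h_hz = noise_sd_h_hz, noise_sd_n_hz = noise_sd_n_hz,
      linewidth_h_hz = linewidth_h_hz, linewidth_n_hz = linewidth_n_hz,
      snr = snr, field_MHz = field_MHz, seed = seed
    ),
    class = "titration_sim_spec"
  )
}

#' Default per-residue truth table for titration simulation
#'
#' The responsive set is the eight-residue binding footprint reported for
#' the strongest compound class (W60/N61 in D2.1, E75/W76/Q77 in D2.2 and
#' F87/Y88/Y89 in D2.3), embedded in an otherwise unresponsive kinase
#' inhibitory domain (residues 23-104). Maximum 1H shift changes are spread
#' over 60-160 Hz, chosen so that the observed endpoint displacements of
#' the responsive residues span roughly 0.03-0.12 ppm at 800 MHz for
#' millimolar-range dissociation constants — the magnitude range the
#' study's per-residue binding isotherms display; 15N
#' responses are scaled to 30% of the 1H response, mirroring the
#' observation that amide-proton perturbations dominate. The tryptophan
#' indole NH side-chain resonances (`"s-60"`, `"s-76"`), which the
#' titration spectra show as strong responders, ride along as extra rows
#' at the top of the amplitude range. Free-state positions are evenly
#' spread across the amide region.
#'
#' @param responsive Residue numbers that respond to ligand.
#' @param flat Residue numbers that do not.
#' @param delta_max_h_hz Maximum 1H shift changes (Hz) for the responsive
#'   residues (recycled to length).
#' @param side_chain Labels of responsive side-chain NH rows.
#' @param side_chain_delta_max_h_hz Their maximum 1H shift changes (Hz).
#' @return Tibble usable as the `residues` field of [titration_sim_spec()].
#' @export
default_titration_residues <- function(responsive = c(60, 61, 75, 76, 77, 87, 88, 89),
                                       flat = setdiff(23:104, responsive),
                                       delta_max_h_hz = seq(60, 160, length.out = length(responsive)),
                                       side_chain = c("s-60", "s-76"),
                                       side_chain_delta_max_h_hz = c(140, 160)) {
  all_res <- c(as.character(c(responsive, flat)), side_chain)
  dmax_h <- c(rep_len(delta_max_h_hz, length(responsive)), rep(0, length(flat)),
              rep_len(side_chain_delta_max_h_hz, length(side_chain)))
  n <- length(all_res)
  tibble(
    residue = all_res,
    delta_max_h_hz = dmax_h,
    delta_max_n_hz = 0.3 * dmax_h,
    dh_free_ppm = c(seq(7.6, 8.7, length.out = n - length(side_chain)),
                    seq(10.0, 10.2, length.out = length(side_chain))),
    dn_free_ppm = c(seq(106, 129, length.out = n - length(side_chain)),
                    seq(129.3, 129.8, length.out = length(side_chain)))
  ) %>% arrange(.data$residue)
}

#' Simulate a fast-exchange titration series
#'
#' Generates per-residue observed shift displacements across the ladder. For
#' residue r at ladder point i the observed displacement from the free-state
#' position is \eqn{f_b(L_i) \Delta\delta_{max,r} + \epsilon}, with the bound
#' fraction from the exact 1:1 depletion model ([fraction_bound()]) and
#' additive Gaussian position noise per dimension (every point, including the
#' ligand-free one, is "measured" with noise). The reported per-point
#' position uncertainty is linewidth / SNR ([peak_position_error()]).
#'
#' @param spec A [titration_sim_spec()].
#' @return A `titration_series`: long tibble with columns `residue`, `point`,
#'   `ratio`, `l_tot_uM`, `dim` ("H"/"N"), `shift_hz` (observed displacement
#'   from the free-state position) and `sigma_hz`. Attributes: `p_tot_uM`,
#'   `field_MHz`, and `truth` (the spec, including `kd_true_uM`).
#' @examples
#' series <- simulate_titration(titration_sim_spec(seed = 7))
#' @export
simulate_titration <- function(spec) {
  if (!inherits(spec, "titration_sim_spec")) {
    abort("`spec` must be created by titration_sim_spec()")
  }
  p <- spec$protein_total_uM
  l <- spec$molar_ratios * p
  kd_um <- spec$kd_true_mM * 1000
  fb <- fraction_bound(p, l, kd_um)
  res <- spec$residues
  grid <- tidyr::expand_grid(
    residue = res$residue,
    point = seq_along(l)
  ) %>%
    left_join(res, by = "residue") %>%
    mutate(
      ratio = spec$molar_ratios[.data$point],
      l_tot_uM = l[.data$point],
      f_bound = fb[.data$point]
    )
  out <- with_sim_seed(spec$seed, {
    n <- nrow(grid)
    grid %>%
      mutate(
        shift_h = .data$f_bound * .data$delta_max_h_hz +
          rnorm(n, 0, spec$noise_sd_h_hz),
        shift_n = .data$f_bound * .data$delta_max_n_hz +
          rnorm(n, 0, spec$noise_sd_n_hz)
      )
  })
  long <- out %>%
    select("residue", "point", "ratio", "l_tot_uM", "shift_h", "shift_n") %>%
    tidyr::pivot_longer(c("shift_h", "shift_n"),
                        names_to = "dim", values_to = "shift_hz") %>%
    mutate(
      dim = ifelse(.data$dim == "shift_h", "H", "N"),
      sigma_hz = peak_position_error(
        ifelse(.data$dim == "H", spec$linewidth_h_hz, spec$linewidth_n_hz),
        spec$snr
      )
    ) %>%
    arrange(.data$dim, .data$residue, .data$point)
  new_titration_series(long, p_tot_uM = p, field_MHz = spec$field_MHz,
                       truth = c(spec, list(kd_true_uM = kd_um)))
}

#' @noRd
new_titration_series <- function(df, p_tot_uM, field_MHz, truth = NULL) {
  out <- as_tibble(df)
  attr(out, "p_tot_uM") <- p_tot_uM
  attr(out, "field_MHz") <- field_MHz
  attr(out, "truth") <- truth
  class(out) <- c("titration_series", class(out))
  out
}

#' Convert a titration series to reference/endpoint peak lists
#'
#' Reconstructs absolute peak lists (ppm) for two ladder points of a
#' simulated titration so the chemical-shift-perturbation significance
#' machinery can be exercised on it exactly as on measured peak lists.
#'
#' @param series A `titration_series` from [simulate_titration()].
#' @param points Two ladder point indices (default first and last).
#' @return List of two [peak_list()] tibbles named `reference`, `perturbed`.
#' @export
titration_peak_lists <- function(series, points = NULL) {
  truth <- attr(series, "truth")
  if (is.null(truth)) abort("`series` lacks generator truth; was it simulated?")
  field <- attr(series, "field_MHz")
  points <- points %||% c(min(series$point), max(series$point))
  res <- truth$residues
  make_one <- function(pt) {
    wide <- series %>%
      filter(.data$point == pt) %>%
      tidyr::pivot_wider(id_cols = "residue", names_from = "dim",
                         values_from = "shift_hz") %>%
      left_join(res, by = "residue") %>%
      mutate(
        dH_ppm = .data$dh_free_ppm + .data$H / field,
        dN_ppm = .data$dn_free_ppm + .data$N / (field * GAMMA_N_OVER_H)
      ) %>%
      mutate(
        intensity = 1, lw_H_hz = truth$linewidth_h_hz,
        lw_N_hz = truth$linewidth_n_hz, snr = truth$snr
      ) %>%
      select("residue", "dH_ppm", "dN_ppm", "intensity",
             "lw_H_hz", "lw_N_hz", "snr")
    peak_list(wide, field_MHz = field)
  }
  list(reference = make_one(points[1]), perturbed = make_one(points[2]))
}

#' Specification for a two-state distance trajectory
#'
#' Describes pairwise-distance dynamics that alternate between a compact and
#' an extended conformational state. The hidden state follows a symmetric
#' two-state Markov chain in discrete frames with expected residence
#' `dwell_frames`; while a state is active, each configured residue pair's
#' distance is drawn from that state's Gaussian.
#'
#' The default pair table emulates the aromatic-cluster dynamics of the p27
#' D2 sub-domain: the W60-W76 distance samples a narrow unimodal range
#' (16.5 +/- 2.3 A in both states) while the two Y88 distances are bimodal;
#' their per-state parameters are chosen so that the equal-occupancy mixture
#' reproduces the reported marginal statistics (20.5 +/- 5.5 A for W60-Y88
#' and 19.6 +/- 4.0 A for W76-Y88).
#'
#' @param pairs Tibble with columns `pair`, `mean_compact_A`, `sd_compact_A`,
#'   `mean_extended_A`, `sd_extended_A` (means/SDs in Angstrom, > 0 means,
#'   >= 0 SDs).
#' @param dwell_frames Expected state residence in frames (> 0; `Inf` pins
#'   the chain in its initial state).
#' @param frame_ps Frame interval (ps).
#' @param n_frames Number of frames (>= 1).
#' @param init_state `"random"`, `"compact"` or `"extended"`.
#' @param seed RNG seed.
#' @return A `two_state_spec` list.
#' @export
two_state_spec <- function(pairs = default_two_state_pairs(),
                           dwell_frames = 5000, frame_ps = 2,
                           n_frames = 200000L,
                           init_state = c("random", "compact", "extended"),
                           seed = 1L) {
  init_state <- match.arg(init_state)
  pairs <- as_tibble(pairs)
  needed <- c("pair", "mean_compact_A", "sd_compact_A",
              "mean_extended_A", "sd_extended_A")
  if (!all(needed %in% names(pairs))) {
    abort(paste0("`pairs` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(pairs$mean_compact_A <= 0) || any(pairs$mean_extended_A <= 0)) {
    abort("state means must be positive")
  }
  if (any(pairs$sd_compact_A < 0) || any(pairs$sd_extended_A < 0)) {
    abort("state SDs must be non-negative")
  }
  assert_number(dwell_frames, "dwell_frames", lower = 0, strict = TRUE, allow_na = FALSE)
  assert_number(frame_ps, "frame_ps", lower = 0, strict = TRUE)
  assert_number(n_frames, "n_frames", lower = 1)
  structure(
    list(pairs = pairs, dwell_frames = dwell_frames, frame_ps = frame_ps,
         n_frames = as.integer(n_frames), init_state = init_state, seed = seed),
    class = "two_state_spec"
  )
}

#' Default per-state distance parameters for the aromatic-cluster pairs
#'
#' @return Tibble of per-state Gaussian parameters for the three Cbeta pairs
#'   among W60, W76 and Y88 (see [two_state_spec()] for the rationale).
#' @export
default_two_state_pairs <- function() {
  tibble(
    pair = c("W60_W76", "W60_Y88", "W76_Y88"),
    mean_compact_A = c(16.5, 15.9, 16.3),
    sd_compact_A = c(2.3, 2.8, 2.0),
    mean_extended_A = c(16.5, 25.1, 22.9),
    sd_extended_A = c(2.3, 3.2, 2.6)
  )
}

#' Simulate a two-state pairwise-distance trajectory
#'
#' Generates the hidden compact/extended state chain and per-frame Gaussian
#' distances for each configured pair. True state labels are retained so
#' classification can be scored against them.
#'
#' @param spec A [two_state_spec()].
#' @return A `distance_state_series`: tibble with `frame`, `time_ps`,
#'   `state_true` and one `d_<pair>` column (Angstrom) per configured pair.
#'   Attributes: `truth` (the spec), `span_ns`, `frame_ps`.
#' @examples
#' traj <- simulate_two_state_trajectory(two_state_spec(n_frames = 1000))
#' @export
simulate_two_state_trajectory <- function(spec) {
  if (!inherits(spec, "two_state_spec")) {
    abort("`spec` must be created by two_state_spec()")
  }
  n <- spec$n_frames
  p_switch <- if (is.infinite(spec$dwell_frames)) 0 else
    min(1, 1 / spec$dwell_frames)
  out <- with_sim_seed(spec$seed, {
    s0 <- switch(spec$init_state,
      random = sample(c(0L, 1L), 1),
      compact = 0L,
      extended = 1L
    )
    flips <- if (n > 1) as.integer(runif(n - 1) < p_switch) else integer(0)
    state <- (s0 + cumsum(c(0L, flips))) %% 2L  # 0 = compact, 1 = extended
    cols <- purrr::pmap(spec$pairs, function(pair, mean_compact_A, sd_compact_A,
                                             mean_extended_A, sd_extended_A) {
      mu <- ifelse(state == 0L, mean_compact_A, mean_extended_A)
      sdv <- ifelse(state == 0L, sd_compact_A, sd_extended_A)
      rnorm(n, mu, sdv)
    })
    names(cols) <- paste0("d_", spec$pairs$pair)
    dplyr::bind_cols(
      tibble(
        frame = seq_len(n),
        time_ps = (seq_len(n) - 1) * spec$frame_ps,
        state_true = ifelse(state == 0L, "compact", "extended")
      ),
      as_tibble(cols)
    )
  })
  attr(out, "truth") <- spec
  attr(out, "frame_ps") <- spec$frame_ps
  attr(out, "span_ns") <- n * spec$frame_ps / 1000
  class(out) <- c("distance_state_series", class(out))
  out
}

#' Specification for a synthetic combinatorial fragment library
#'
#' Builds a scaffold x substituent library with controlled per-scaffold
#' multiplicities, optionally salted with decoys (invalid, inorganic or
#' isotope-containing entries) so the curation pipeline's verdicts can be
#' scored against ground truth. Substituents are attached by SMILES
#' concatenation, so each substituent must be written with its attachment
#' atom last (e.g. `"CC"` attaches an ethyl).
#'
#' @param scaffolds Named character vector of scaffold SMILES (names become
#'   scaffold labels). Each must start with a ring-atom token so
#'   concatenation forms a bond to the ring.
#' @param substituents Character vector of substituent SMILES prefixes; may
#'   be empty (bare scaffolds).
#' @param multiplicity Named integer vector: members per scaffold (>= 0),
#'   names matching `scaffolds`.
#' @param decoy_fraction Fraction of the emitted library that is decoys, in
#'   \[0, 1). The decoy count is `round(f/(1-f) * n_members)` so that decoys
#'   make up the requested fraction of the total.
#' @param decoy_types Types to cycle through: subset of
#'   `c("invalid", "inorganic", "isotope")`.
#' @param seed RNG seed (used for substituent assignment and decoy order).
#' @return A `library_sim_spec` list.
#' @export
library_sim_spec <- function(scaffolds = c(
                               quinoline = "c1ccc2ncccc2c1",
                               indole = "c1ccc2[nH]ccc2c1",
                               benzothiazole = "c1ccc2sc(nc2c1)",
                               benzene = "c1ccccc1"
                             ),
                             substituents = c("C", "CC", "OC", "N#C", "FC(F)(F)", "OCC"),
                             multiplicity = c(quinoline = 9, indole = 8,
                                              benzothiazole = 7, benzene = 5),
                             decoy_fraction = 0,
                             decoy_types = c("invalid", "inorganic", "isotope"),
                             seed = 1L) {
  if (is.null(names(scaffolds)) || any(names(scaffolds) == "")) {
    abort("`scaffolds` must be a named character vector")
  }
  if (!all(names(multiplicity) %in% names(scaffolds))) {
    abort("`multiplicity` names must match scaffold names")
  }
  if (any(multiplicity < 0)) abort("multiplicities must be >= 0")
  assert_number(decoy_fraction, "decoy_fraction", lower = 0)
  if (decoy_fraction >= 1) abort("`decoy_fraction` must be < 1")
  decoy_types <- match.arg(decoy_types, several.ok = TRUE)
  structure(
    list(scaffolds = scaffolds, substituents = substituents,
         multiplicity = multiplicity, decoy_fraction = decoy_fraction,
         decoy_types = decoy_types, seed = seed),
    class = "library_sim_spec"
  )
}

# Fixed decoy templates, one per kind of rejection the sanitizer must make.
DECOY_TEMPLATES <- list(
  invalid = c("C1CC(", "c1ccccc", "XZQ"),
  inorganic = c("[Fe+2]", "C[Si](C)(C)C", "[Na+].[Cl-]"),
  isotope = c("[13CH4]", "[2H]OC1=CC=CC=C1", "[15NH3]")
)

#' Simulate a combinatorial fragment library with ground truth
#'
#' Emits one SMILES entry per requested scaffold member (scaffold plus a
#' cycled/random substituent), plus the requested decoys, together with a
#' mock screening-collection frequency table in which each scaffold's count
#' equals its requested multiplicity. Ground-truth columns record what the
#' sanitizer and the scaffold-frequency filter should decide for each entry.
#'
#' @param spec A [library_sim_spec()].
#' @return A `library_sim`: list with `compounds` (tibble: `id`, `smiles`,
#'   `scaffold`, `is_decoy`, `decoy_type`, `truth_sanitize`,
#'   `truth_freq_pass`) and `hts_frequencies` (tibble: `scaffold_smiles`,
#'   `count`, `scaffold`).
#' @export
simulate_library <- function(spec) {
  if (!inherits(spec, "library_sim_spec")) {
    abort("`spec` must be created by library_sim_spec()")
  }
  # validate scaffold/substituent parseability up front, naming offenders
  for (nm in names(spec$scaffolds)) {
    if (!smiles_parses(spec$scaffolds[[nm]])) {
      abort(sprintf("scaffold '%s' is not parseable SMILES: %s",
                    nm, spec$scaffolds[[nm]]))
    }
  }
  for (s in spec$substituents) {
    if (!smiles_parses(paste0(s, "c1ccccc1"))) {
      abort(sprintf("substituent is not attachable SMILES: %s", s))
    }
  }
  with_sim_seed(spec$seed, {
    members <- purrr::map_dfr(names(spec$multiplicity), function(nm) {
      m <- spec$multiplicity[[nm]]
      if (m == 0) return(tibble())
      subs <- if (length(spec$substituents) == 0) {
        rep("", m)
      } else {
        # cycle then shuffle so every substituent is represented
        sample(rep_len(spec$substituents, m))
      }
      tibble(
        scaffold = nm,
        smiles = paste0(subs, spec$scaffolds[[nm]]),
        truth_freq_pass = m >= 8
      )
    })
    n_members <- nrow(members)
    n_decoys <- round(spec$decoy_fraction / (1 - spec$decoy_fraction) * n_members)
    decoys <- if (n_decoys > 0) {
      types <- rep_len(spec$decoy_types, n_decoys)
      tibble(
        scaffold = NA_character_,
        smiles = purrr::map2_chr(types, seq_len(n_decoys), function(tp, i) {
          tpl <- DECOY_TEMPLATES[[tp]]
          tpl[((i - 1) %% length(tpl)) + 1]
        }),
        truth_freq_pass = FALSE,
        decoy_type = types
      )
    } else {
      tibble()
    }
    compounds <- bind_rows(
      members %>% mutate(is_decoy = FALSE, decoy_type = NA_character_),
      decoys %>% mutate(is_decoy = TRUE)
    ) %>%
      mutate(
        id = sprintf("CMP%04d", row_number()),
        truth_sanitize = ifelse(.data$is_decoy, .data$decoy_type, "valid")
      ) %>%
      select("id", "smiles", "scaffold", "is_decoy", "decoy_type",
             "truth_sanitize", "truth_freq_pass")
    freq <- tibble(
      scaffold = names(spec$multiplicity),
      count = as.integer(spec$multiplicity)
    ) %>%
      mutate(scaffold_smiles = purrr::map_chr(
        .data$scaffold,
        function(nm) murcko_scaffold(spec$scaffolds[[nm]], keep_alpha = FALSE)$scaffold_smiles
      )) %>%
      select("scaffold_smiles", "count", "scaffold")
    structure(list(compounds = compounds, hts_frequencies = freq),
              class = "library_sim")
  })
}

#' Simulate a saturation fluorescence-anisotropy ladder
#'
#' Generates anisotropy readings for a fixed fluorescent probe titrated with
#' its binding partner, under the exact 1:1 depletion model plus Gaussian
#' noise expressed as a fraction of the anisotropy dynamic range. Replicate
#' readings are averaged; their SD is reported per point.
#'
#' Defaults emulate the displacement study's direct-binding experiment:
#' 20 nM labelled probe domain, nanomolar-range receptor ladder, ground
#' truth K_d 73 nM.
#'
#' @param conc_nM Titrant concentration ladder (strictly increasing, >= 0).
#' @param kd_true_nM Ground-truth dissociation constant (nM).
#' @param probe_nM Probe total (nM).
#' @param r_free,r_bound Anisotropy of the free and bound probe.
#' @param noise_frac Gaussian noise SD as a fraction of `r_bound - r_free`.
#' @param n_rep Number of replicates averaged per point.
#' @param seed RNG seed.
#' @return An `anisotropy_series` tibble: `conc`, `response`, `sd`, with
#'   attributes `probe_tot` and `truth`.
#' @export
simulate_anisotropy <- function(conc_nM = c(0, 10, 25, 50, 75, 100, 150, 200,
                                            300, 450, 700, 1000, 1500),
                                kd_true_nM = 73, probe_nM = 20,
                                r_free = 0.06, r_bound = 0.22,
                                noise_frac = 0.02, n_rep = 3, seed = 1L) {
  if (is.unsorted(conc_nM, strictly = TRUE)) {
    abort("`conc_nM` must be strictly increasing")
  }
  if (any(conc_nM < 0)) abort("concentrations must be >= 0")
  assert_number(kd_true_nM, "kd_true_nM", lower = 0, strict = TRUE)
  assert_number(probe_nM, "probe_nM", lower = 0, strict = TRUE)
  assert_number(noise_frac, "noise_frac", lower = 0)
  r_true <- r_free + (r_bound - r_free) * fraction_bound(probe_nM, conc_nM, kd_true_nM)
  noise_sd <- noise_frac * abs(r_bound - r_free)
  out <- with_sim_seed(seed, {
    reps <- matrix(
      rnorm(length(conc_nM) * n_rep, mean = rep(r_true, n_rep), sd = noise_sd),
      ncol = n_rep
    )
    tibble(
      conc = conc_nM,
      response = rowMeans(reps),
      sd = apply(reps, 1, stats::sd)
    )
  })
  attr(out, "probe_tot") <- probe_nM
  attr(out, "truth") <- list(kd_true = kd_true_nM, r_free = r_free,
                             r_bound = r_bound, noise_frac = noise_frac,
                             n_rep = n_rep, seed = seed)
  class(out) <- c("anisotropy_series", class(out))
  out
}

#' Simulate a four-parameter-logistic dose-response curve
#'
#' Generates replicate responses on a 4PL curve with Gaussian noise
#' proportional to the response range, then averages replicates (curve
#' fitting on the replicate average mirrors common plate-assay practice).
#'
#' @param conc Dose ladder (strictly increasing, > 0).
#' @param ic50_true Ground-truth half-maximal concentration (same unit).
#' @param hill Hill slope.
#' @param top,bottom Upper/lower response asymptotes.
#' @param noise_frac Gaussian noise SD as a fraction of `|top - bottom|`.
#' @param n_rep Replicates averaged per dose.
#' @param seed RNG seed.
#' @return A `dose_response_series` tibble: `conc`, `response`, `sd`, with
#'   attribute `truth`.
#' @export
simulate_dose_response <- function(conc, ic50_true, hill = 1,
                                   top = 100, bottom = 0,
                                   noise_frac = 0.03, n_rep = 3, seed = 1L) {
  if (any(conc <= 0)) abort("doses must be > 0")
  if (is.unsorted(conc, strictly = TRUE)) abort("`conc` must be strictly increasing")
  assert_number(ic50_true, "ic50_true", lower = 0, strict = TRUE)
  assert_number(noise_frac, "noise_frac", lower = 0)
  y_true <- bottom + (top - bottom) / (1 + (conc / ic50_true)^hill)
  noise_sd <- noise_frac * abs(top - bottom)
  out <- with_sim_seed(seed, {
    reps <- matrix(
      rnorm(length(conc) * n_rep, mean = rep(y_true, n_rep), sd = noise_sd),
      ncol = n_rep
    )
    tibble(conc = conc, response = rowMeans(reps),
           sd = apply(reps, 1, stats::sd))
  })
  attr(out, "truth") <- list(ic50_true = ic50_true, hill = hill, top = top,
                             bottom = bottom, noise_frac = noise_frac,
                             n_rep = n_rep, seed = seed)
  class(out) <- c("dose_response_series", class(out))
  out
}

#' Simulate free/bound peak doublets for a displacement experiment
#'
#' Emits replicate free/bound intensity doublets for each residue under two
#' conditions (without and with a displacing compound), given the true free
#' populations in each condition. Total intensity is arbitrary and noise is
#' multiplicative log-normal-ish (Gaussian on intensities, floored at 0).
#'
#' @param residues Residue labels.
#' @param p_free_without,p_free_with True free-state populations per residue
#'   (recycled), each in \[0, 1\].
#' @param total_intensity Mean total doublet intensity.
#' @param noise_frac Gaussian intensity noise SD as a fraction of intensity.
#' @param n_rep Replicates per condition.
#' @param seed RNG seed.
#' @return Tibble: `residue`, `condition` ("without"/"with"), `replicate`,
#'   `I_free`, `I_bound`, with attribute `truth`.
#' @export
simulate_displacement <- function(residues = c("53", "55", "62", "75", "93"),
                                  p_free_without = 0.25, p_free_with = 0.55,
                                  total_intensity = 1000, noise_frac = 0.05,
                                  n_rep = 3, seed = 1L) {
  pf0 <- rep_len(p_free_without, length(residues))
  pf1 <- rep_len(p_free_with, length(residues))
  if (any(c(pf0, pf1) < 0 | c(pf0, pf1) > 1)) abort("populations must lie in [0, 1]")
  grid <- tidyr::expand_grid(
    residue = as.character(residues),
    condition = c("without", "with"),
    replicate = seq_len(n_rep)
  ) %>%
    mutate(p_free = ifelse(.data$condition == "without",
                           pf0[match(.data$residue, as.character(residues))],
                           pf1[match(.data$residue, as.character(residues))]))
  out <- with_sim_seed(seed, {
    n <- nrow(grid)
    grid %>%
      mutate(
        I_free = pmax(rnorm(n, total_intensity * .data$p_free,
                            noise_frac * total_intensity * .data$p_free), 0),
        I_bound = pmax(rnorm(n, total_intensity * (1 - .data$p_free),
                             noise_frac * total_intensity * (1 - .data$p_free)), 0)
      ) %>%
      select("residue", "condition", "replicate", "I_free", "I_bound")
  })
  attr(out, "truth") <- list(p_free_without = pf0, p_free_with = pf1,
                             residues = as.character(residues), seed = seed)
  out
}
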