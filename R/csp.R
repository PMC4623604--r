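# Chemical-shift-perturbation analysis: per-residue shift differences from
# 2D 1H-15N peak lists, dual significance criterion (resolution floor AND
# mean + 2 SD), and binding-site pattern classification.

#' Construct a peak list
#'
#' Validates and tags a per-residue peak table from a 2D 1H-15N correlation
#' spectrum. Residue labels are character so side-chain resonances (e.g. the
#' tryptophan indole NH of residue 60, keyed `"s-60"`) can ride along with
#' backbone amides; the numeric part is recovered where region mapping needs
#' it.
#'
#' @param df Data frame with columns `residue`, `dH_ppm`, `dN_ppm`,
#'   `intensity`, `lw_H_hz`, `lw_N_hz`, `snr`.
#' @param field_MHz Spectrometer 1H frequency (MHz, > 0).
#' @return A `peak_list` tibble with attribute `field_MHz`.
#' @export
peak_list <- function(df, field_MHz) {
  assert_number(field_MHz, "field_MHz", lower = 0, strict = TRUE)
  df <- as_tibble(df)
  needed <- c("residue", "dH_ppm", "dN_ppm", "intensity", "lw_H_hz", "lw_N_hz", "snr")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("peak list is missing columns: ", paste(missing, collapse = ", ")))
  }
  df$residue <- as.character(df$residue)
  if (anyDuplicated(df$residue)) abort("residue labels must be unique in a peak list")
  out <- df[, needed]
  attr(out, "field_MHz") <- field_MHz
  class(out) <- c("peak_list", class(out))
  out
}

#' Read / write a peak-list TSV
#'
#' The on-disk format is tab-separated with a comment header carrying the
#' field strength: a first line `# field_MHz=<f>` followed by the column
#' header `residue dH_ppm dN_ppm intensity lw_H_hz lw_N_hz snr`.
#'
#' @param path File path.
#' @return [read_peak_list()] returns a `peak_list`;
#'   [write_peak_list()] returns `path` invisibly.
#' @export
read_peak_list <- function(path) {
  first <- readLines(path, n = 1L)
  m <- stringr::str_match(first, "field_MHz\\s*=\\s*([0-9.]+)")
  if (is.na(m[1, 2])) abort("peak-list file lacks a '# field_MHz=' header line")
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(residue = readr::col_character()))
  peak_list(df, field_MHz = as.numeric(m[1, 2]))
}

#' @rdname read_peak_list
#' @param x A `peak_list`.
#' @export
write_peak_list <- function(x, path) {
  if (!inherits(x, "peak_list")) abort("`x` must be a peak_list")
  writeLines(sprintf("# field_MHz=%g", attr(x, "field_MHz")), path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Compute per-residue chemical shift perturbations
#'
#' Computes the absolute per-dimension shift difference between a reference
#' (typically ligand-free) and a perturbed peak list, in both ppm and Hz.
#' Hz values use the nucleus Larmor frequency: the spectrometer 1H frequency
#' for the 1H dimension and its 15N equivalent (1H frequency times the
#' gyromagnetic-ratio quotient, about 0.1014) for the 15N dimension, so that
#' digital-resolution floors quoted in Hz apply directly. The two dimensions
#' are kept separate throughout; no combined-shift collapse is applied by
#' default because proton perturbations dominate in this regime and a
#' combined value would dilute them (see [combined_csp()] for the opt-in).
#'
#' Residues present in only one list are dropped with a message.
#'
#' @param reference,perturbed [peak_list()]s sharing residue labelling and
#'   field strength.
#' @return A `csp_profile` tibble: `residue`, `dd_h_ppm`, `dd_h_hz`,
#'   `dd_n_ppm`, `dd_n_hz`; attributes `field_MHz`, `dropped`.
#' @export
compute_csp <- function(reference, perturbed) {
  for (x in list(reference, perturbed)) {
    if (!inherits(x, "peak_list")) abort("inputs must be peak_list objects")
  }
  f1 <- attr(reference, "field_MHz"); f2 <- attr(perturbed, "field_MHz")
  if (!isTRUE(all.equal(f1, f2))) {
    abort(sprintf("field-strength mismatch: %g vs %g MHz", f1, f2))
  }
  common <- intersect(reference$residue, perturbed$residue)
  dropped <- setdiff(union(reference$residue, perturbed$residue), common)
  if (length(dropped) > 0) {
    inform(paste0("residues present in only one list were omitted: ",
                  paste(dropped, collapse = ", ")))
  }
  ref <- as_tibble(reference)[match(common, reference$residue), ]
  per <- as_tibble(perturbed)[match(common, perturbed$residue), ]
  out <- tibble(
    residue = common,
    dd_h_ppm = abs(per$dH_ppm - ref$dH_ppm),
    dd_n_ppm = abs(per$dN_ppm - ref$dN_ppm)
  ) %>%
    mutate(
      dd_h_hz = .data$dd_h_ppm * f1,
      dd_n_hz = .data$dd_n_ppm * f1 * GAMMA_N_OVER_H
    ) %>%
    select("residue", "dd_h_ppm", "dd_h_hz", "dd_n_ppm", "dd_n_hz")
  attr(out, "field_MHz") <- f1
  attr(out, "dropped") <- dropped
  class(out) <- c("csp_profile", class(out))
  out
}

#' Combined 1H/15N chemical shift perturbation (opt-in)
#'
#' The conventional combined value
#' \eqn{\sqrt{(\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2)/2}} in ppm.
#' Provided for comparison only; the significance machinery works per
#' dimension by default.
#'
#' @param profile A `csp_profile`.
#' @param alpha 15N scaling weight (default 0.14).
#' @return The profile with an extra `dd_combined_ppm` column.
#' @export
combined_csp <- function(profile, alpha = 0.14) {
  if (!inherits(profile, "csp_profile")) abort("`profile` must be a csp_profile")
  profile %>%
    mutate(dd_combined_ppm = sqrt((.data$dd_h_ppm^2 + (alpha * .data$dd_n_ppm)^2) / 2))
}

#' Flag significant chemical shift perturbations
#'
#' A residue's perturbation in a given dimension is significant iff it
#' strictly exceeds BOTH (i) the spectral resolution floor of that dimension
#' and (ii) the dimension's mean perturbation plus twice its dispersion
#' (`mean + 2 sigma`), with statistics computed over all residues observed in
#' that dimension. The dispersion is the sample SD by default; `stat = "sem"`
#' substitutes the standard error of the mean.
#'
#' @param profile A `csp_profile` from [compute_csp()].
#' @param resolution_h_hz,resolution_n_hz Digital resolution floors (Hz).
#' @param stat `"sd"` (default) or `"sem"`.
#' @return The profile with logical columns `sig_h`, `sig_n` and attribute
#'   `csp_stats` (per-dimension mean, dispersion, threshold, floor).
#' @export
flag_significant <- function(profile, resolution_h_hz = 2.4,
                             resolution_n_hz = 1.7, stat = c("sd", "sem")) {
  if (!inherits(profile, "csp_profile")) abort("`profile` must be a csp_profile")
  stat <- match.arg(stat)
  assert_number(resolution_h_hz, "resolution_h_hz", lower = 0)
  assert_number(resolution_n_hz, "resolution_n_hz", lower = 0)
  dims <- list(
    H = list(dd = profile$dd_h_hz, floor = resolution_h_hz),
    N = list(dd = profile$dd_n_hz, floor = resolution_n_hz)
  )
  stats_tbl <- purrr::imap_dfr(dims, function(d, nm) {
    dd <- d$dd[is.finite(d$dd)]
    if (length(dd) < 3) {
      abort("need at least 3 residues with finite perturbations per dimension")
    }
    sigma <- stats::sd(dd)
    if (stat == "sem") sigma <- sigma / sqrt(length(dd))
    tibble(dim = nm, mean_hz = mean(dd), sigma_hz = sigma,
           threshold_hz = mean(dd) + 2 * sigma, floor_hz = d$floor, n = length(dd))
  })
  thr <- function(nm) stats_tbl$threshold_hz[stats_tbl$dim == nm]
  flo <- function(nm) stats_tbl$floor_hz[stats_tbl$dim == nm]
  out <- profile %>%
    mutate(
      sig_h = is.finite(.data$dd_h_hz) &
        .data$dd_h_hz > flo("H") & .data$dd_h_hz > thr("H"),
      sig_n = is.finite(.data$dd_n_hz) &
        .data$dd_n_hz > flo("N") & .data$dd_n_hz > thr("N")
    )
  attr(out, "csp_stats") <- stats_tbl
  attr(out, "field_MHz") <- attr(profile, "field_MHz")
  class(out) <- unique(c("csp_profile", class(out)))
  out
}

#' Sub-region map of the kinase-binding D2 sub-domain
#'
#' Named residue ranges for the three small-molecule interaction sub-regions
#' of the p27 D2 sub-domain, in full-length human p27 numbering. The study
#' localises them by marker residues (W60/N61 for D2.1, E75/W76/Q77 for
#' D2.2, F87/Y88/Y89 for D2.3); the default ranges extend those markers
#' symmetrically and are overridable.
#'
#' @param d2_1,d2_2,d2_3 Integer residue ranges.
#' @return A `subregion_map` list with validated, non-overlapping ranges.
#' @export
subregion_map <- function(d2_1 = 58:70, d2_2 = 71:81, d2_3 = 85:90) {
  regions <- list(d2_1 = d2_1, d2_2 = d2_2, d2_3 = d2_3)
  all_res <- unlist(regions)
  if (anyDuplicated(all_res)) abort("sub-region ranges must not overlap")
  structure(regions, class = "subregion_map",
            markers = c(d2_1 = 60L, d2_2 = 76L, d2_3 = 88L))
}

#' @noRd
residue_number <- function(residue) {
  suppressWarnings(as.integer(stringr::str_remove(residue, "^s-")))
}

#' Classify a compound's binding-site pattern
#'
#' Sorts a flagged perturbation profile into the study's binding classes:
#' `"group1"` if significant residues fall only within sub-region D2.3 (the
#' FYY aromatic cluster), `"group2"` if D2.3 plus at least one of D2.1/D2.2
#' (the tryptophan sub-regions) are hit, `"nonbinder"` if nothing is
#' flagged, and `"ambiguous"` otherwise (e.g. flags outside the mapped
#' sub-regions, or tryptophan sub-regions without D2.3).
#'
#' Side-chain rows (`"s-60"`) count toward their parent residue's region.
#'
#' @param profile A flagged `csp_profile` (see [flag_significant()]).
#' @param map A [subregion_map()].
#' @param dims Dimensions whose flags count (default `"H"`; the proton
#'   dimension carries the discriminating signal in this regime).
#' @return One-row tibble: `class`, counts per sub-region, `n_outside`,
#'   and the list-column `significant` of flagged residue labels.
#' @export
classify_binding_pattern <- function(profile, map = subregion_map(), dims = "H") {
  if (!inherits(profile, "csp_profile")) abort("`profile` must be a csp_profile")
  if (!all(c("sig_h", "sig_n") %in% names(profile))) {
    abort("`profile` is not flagged; run flag_significant() first")
  }
  if (!inherits(map, "subregion_map")) abort("`map` must be a subregion_map")
  sig <- rep(FALSE, nrow(profile))
  if ("H" %in% dims) sig <- sig | profile$sig_h
  if ("N" %in% dims) sig <- sig | profile$sig_n
  flagged <- profile$residue[sig]
  num <- residue_number(flagged)
  in_1 <- sum(num %in% map$d2_1, na.rm = TRUE)
  in_2 <- sum(num %in% map$d2_2, na.rm = TRUE)
  in_3 <- sum(num %in% map$d2_3, na.rm = TRUE)
  outside <- length(flagged) - in_1 - in_2 - in_3
  class <- if (length(flagged) == 0) {
    "nonbinder"
  } else if (outside > 0) {
    "ambiguous"
  } else if (in_3 > 0 && (in_1 > 0 || in_2 > 0)) {
    "group2"
  } else if (in_3 > 0) {
    "group1"
  } else {
    "ambiguous"
  }
  tibble(
    class = class, n_significant = length(flagged),
    n_d2_1 = in_1, n_d2_2 = in_2, n_d2_3 = in_3, n_outside = outside,
    significant = list(flagged)
  )
}
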