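# Trajectory distance-state analysis: pairwise Cbeta distances over time,
# block averages, compact/extended classification and contact co-occurrence.

#' Configuration for distance-state analysis
#'
#' @param pairs List of length-2 character vectors of residue labels (letter
#'   plus full-length residue number, e.g. `c("W60", "Y88")`), defining the
#'   monitored atom pairs.
#' @param hub Residue label whose contacts define the default compact rule
#'   (see [classify_frames()]).
#' @param cutoff_A Compact-contact distance cutoff (Angstrom, > 0; strict
#'   inequality).
#' @param window_ns Block-averaging window (ns).
#' @param stride_ps Frame interval (ps).
#' @param rule `"hub"`: compact iff the hub residue is within the cutoff of
#'   at least one partner. `"any"`: compact iff any monitored pair is within
#'   the cutoff (the literal two-of-three reading).
#' @param atom Atom name used for distances (default `"CB"`).
#' @param resno_offset Offset added to label numbers to reach the
#'   coordinate file's residue numbering (for truncated constructs).
#' @return A `state_config` list.
#' @export
state_config <- function(pairs = list(c("W60", "W76"), c("W60", "Y88"), c("W76", "Y88")),
                         hub = "Y88", cutoff_A = 20, window_ns = 1,
                         stride_ps = 2, rule = c("hub", "any"),
                         atom = "CB", resno_offset = 0L) {
  rule <- match.arg(rule)
  assert_number(cutoff_A, "cutoff_A", lower = 0, strict = TRUE)
  assert_number(window_ns, "window_ns", lower = 0, strict = TRUE)
  assert_number(stride_ps, "stride_ps", lower = 0, strict = TRUE)
  if (window_ns * 1000 < stride_ps) {
    abort("`window_ns` must be at least one frame interval")
  }
  if (!all(vapply(pairs, length, 1L) == 2L)) {
    abort("each element of `pairs` must name exactly two residues")
  }
  structure(
    list(pairs = pairs, hub = hub, cutoff_A = cutoff_A, window_ns = window_ns,
         stride_ps = stride_ps, rule = rule, atom = atom,
         resno_offset = as.integer(resno_offset)),
    class = "state_config"
  )
}

#' @noRd
label_resno <- function(label, offset = 0L) {
  n <- suppressWarnings(as.integer(stringr::str_extract(label, "[0-9]+")))
  if (any(is.na(n))) abort("residue labels must contain a residue number")
  n + offset
}

#' @noRd
pair_col <- function(pair) paste0("d_", pair[1], "_", pair[2])

#' Extract pairwise distances from a multi-model PDB trajectory
#'
#' Reads every MODEL of a multi-model PDB (via bio3d) and computes the
#' Euclidean distance between the configured atoms of each residue pair per
#' frame. Frame times follow the configured stride.
#'
#' @param trajectory Path to a multi-model PDB file, or a `bio3d` `pdb`
#'   object read with `multi = TRUE`.
#' @param config A [state_config()].
#' @return A `distance_series` tibble: `frame`, `time_ps` and one `d_<A>_<B>`
#'   column per pair (Angstrom). Zero distances are kept but flagged with a
#'   warning (degenerate coordinates).
#' @export
extract_distances <- function(trajectory, config = state_config()) {
  if (is.character(trajectory)) {
    trajectory <- bio3d::read.pdb(trajectory, multi = TRUE)
  }
  if (!inherits(trajectory, "pdb")) abort("`trajectory` must be a PDB path or bio3d pdb object")
  xyz <- trajectory$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  coord_idx <- function(label) {
    resno <- label_resno(label, config$resno_offset)
    sel <- bio3d::atom.select(trajectory, elety = config$atom, resno = resno,
                              verbose = FALSE)
    if (length(sel$xyz) != 3L) {
      abort(sprintf("atom %s of residue %s not found exactly once in the trajectory",
                    config$atom, label))
    }
    sel$xyz
  }
  cols <- purrr::map(config$pairs, function(pr) {
    a <- xyz[, coord_idx(pr[1]), drop = FALSE]
    b <- xyz[, coord_idx(pr[2]), drop = FALSE]
    sqrt(rowSums((a - b)^2))
  })
  names(cols) <- vapply(config$pairs, pair_col, character(1))
  if (any(unlist(cols) == 0)) {
    warn("zero inter-atom distance encountered (degenerate coordinates)")
  }
  out <- dplyr::bind_cols(
    tibble(frame = seq_len(n_frames),
           time_ps = (seq_len(n_frames) - 1) * config$stride_ps),
    as_tibble(cols)
  )
  attr(out, "frame_ps") <- config$stride_ps
  class(out) <- c("distance_series", class(out))
  out
}

#' Read a precomputed distance table
#'
#' CSV with a `time_ps` column and one `d_<A>_<B>` column per pair.
#'
#' @param path CSV path.
#' @return A `distance_series` tibble.
#' @export
read_distance_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_ps" %in% names(df)) abort("distance table needs a time_ps column")
  if (!any(startsWith(names(df), "d_"))) abort("no d_<pair> columns found")
  out <- df %>% mutate(frame = row_number()) %>%
    select("frame", "time_ps", dplyr::starts_with("d_"))
  spacing <- if (nrow(out) > 1) diff(out$time_ps[1:2]) else NA_real_
  attr(out, "frame_ps") <- spacing
  class(out) <- c("distance_series", class(out))
  out
}

#' @noRd
distance_cols <- function(series) {
  names(series)[startsWith(names(series), "d_")]
}

#' Non-overlapping block averages of distance traces
#'
#' Averages each distance column over consecutive non-overlapping windows of
#' the stated length (the "time average every n ns" view). A trailing
#' partial block is averaged over the frames it has and flagged.
#'
#' @param series A `distance_series` (or `distance_state_series`).
#' @param window_ns Window length (ns); must be at least one frame interval.
#' @return Tibble: `block`, `time_ps` (block start), one mean per distance
#'   column, `n_frames`, `partial`.
#' @export
window_average <- function(series, window_ns = 1) {
  series <- as_tibble(series)
  fp <- attr(series, "frame_ps") %||% (if (nrow(series) > 1)
    diff(series$time_ps[1:2]) else abort("cannot infer frame spacing"))
  block_len <- max(1L, round(window_ns * 1000 / fp))
  if (window_ns * 1000 < fp) abort("`window_ns` is shorter than one frame interval")
  dcols <- distance_cols(series)
  out <- series %>%
    mutate(block = (row_number() - 1L) %/% block_len) %>%
    group_by(.data$block) %>%
    summarise(
      time_ps = first(.data$time_ps),
      across(all_of(dcols), mean),
      n_frames = n(), .groups = "drop"
    ) %>%
    mutate(partial = .data$n_frames < block_len)
  if (any(out$partial)) {
    inform(sprintf("trailing partial block averaged over %d frame(s)",
                   out$n_frames[nrow(out)]))
  }
  out
}

#' Classify frames as compact or extended
#'
#' Applies the distance-cutoff rule per frame. Under the default `"hub"`
#' rule a frame is compact iff the hub residue (Y88 by default) is strictly
#' within the cutoff of at least one of its monitored partners; this keys
#' the call on hub-tryptophan contacts rather than on the always-short
#' W60-W76 distance, which would otherwise label nearly every frame
#' compact. The `"any"` rule (any monitored pair strictly within the
#' cutoff) is the literal two-of-three-residues reading and is provided as
#' an alternative.
#'
#' @param series A `distance_series` or `distance_state_series`.
#' @param config A [state_config()].
#' @return The series with a `state` column; attribute `occupancy` (named
#'   fractions summing to 1). Retrieve with [state_occupancy()].
#' @export
classify_frames <- function(series, config = state_config()) {
  series_tbl <- as_tibble(series)
  use_pairs <- if (config$rule == "hub") {
    keep <- vapply(config$pairs, function(p) config$hub %in% p, logical(1))
    if (!any(keep)) abort("no monitored pair involves the hub residue")
    config$pairs[keep]
  } else {
    config$pairs
  }
  cols <- vapply(use_pairs, pair_col, character(1))
  missing <- setdiff(cols, names(series_tbl))
  if (length(missing) > 0) {
    abort(paste0("series lacks distance columns: ", paste(missing, collapse = ", ")))
  }
  dmin <- do.call(pmin, series_tbl[cols])
  state <- ifelse(dmin < config$cutoff_A, "compact", "extended")
  out <- series_tbl %>% mutate(state = state)
  occ <- c(
    compact = mean(state == "compact"),
    extended = mean(state == "extended")
  )
  for (a in c("frame_ps", "span_ns", "truth")) attr(out, a) <- attr(series, a)
  attr(out, "occupancy") <- occ
  class(out) <- unique(c(class(series)[1], "tbl_df", "tbl", "data.frame"))
  if (!inherits(out, "distance_series") && !inherits(out, "distance_state_series")) {
    class(out) <- c("distance_series", class(out))
  }
  out
}

#' @rdname classify_frames
#' @export
state_occupancy <- function(series) {
  occ <- attr(series, "occupancy")
  if (is.null(occ)) {
    if (!"state" %in% names(series)) abort("series has no state labels")
    occ <- c(compact = mean(series$state == "compact"),
             extended = mean(series$state == "extended"))
  }
  occ
}

#' Per-pair distance statistics, histograms and two-state summary
#'
#' Computes sample mean and SD per monitored pair, fixed-bin histograms
#' (default 0.5 Angstrom bins over 0-50 Angstrom), and — when state labels
#' are available or a config is supplied — per-state means/SDs and
#' occupancies (the two-component summary of a bimodal distance
#' distribution).
#'
#' @param series A `distance_series`/`distance_state_series` (>= 2 frames).
#' @param config Optional [state_config()] used to classify frames first if
#'   the series carries no `state` column.
#' @param breaks Histogram bin edges (Angstrom).
#' @return A `distance_stats` list: `summary` (pair, mean_A, sd_A, n),
#'   `histogram` (pair, bin_mid_A, count), `by_state` (or NULL).
#' @export
distance_statistics <- function(series, config = NULL,
                                breaks = seq(0, 50, by = 0.5)) {
  series_tbl <- as_tibble(series)
  if (nrow(series_tbl) < 2) abort("need at least 2 frames")
  if (!"state" %in% names(series_tbl) && !is.null(config)) {
    series_tbl <- as_tibble(classify_frames(series, config))
  }
  dcols <- distance_cols(series_tbl)
  if (length(dcols) == 0) abort("no distance columns found")
  long <- series_tbl %>%
    tidyr::pivot_longer(all_of(dcols), names_to = "pair", values_to = "distance_A") %>%
    mutate(pair = stringr::str_remove(.data$pair, "^d_"))
  summary <- long %>%
    group_by(.data$pair) %>%
    summarise(mean_A = mean(.data$distance_A), sd_A = stats::sd(.data$distance_A),
              n = n(), .groups = "drop")
  histogram <- long %>%
    mutate(bin = cut(.data$distance_A, breaks = breaks, include.lowest = TRUE)) %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$pair, .data$bin) %>%
    summarise(count = n(), .groups = "drop") %>%
    mutate(bin_mid_A = breaks[as.integer(.data$bin)] + diff(breaks)[1] / 2) %>%
    select("pair", "bin_mid_A", "count")
  by_state <- if ("state" %in% names(series_tbl)) {
    long %>%
      group_by(.data$pair, .data$state) %>%
      summarise(mean_A = mean(.data$distance_A), sd_A = stats::sd(.data$distance_A),
                occupancy = n() / nrow(series_tbl), .groups = "drop")
  } else {
    NULL
  }
  structure(list(summary = summary, histogram = histogram, by_state = by_state),
            class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat("Pairwise distance statistics\n")
  print(x$summary)
  if (!is.null(x$by_state)) {
    cat("\nBy state:\n")
    print(x$by_state)
  }
  invisible(x)
}

#' @export
tidy.distance_stats <- function(x, ...) x$summary

#' Contact co-occurrence and distance-trace correlation
#'
#' For every pair of monitored distance traces, reports the fraction of
#' frames in which both are strictly below the contact cutoff, the product
#' of the marginal contact fractions (the independence expectation), and the
#' Pearson correlation of the traces (NA with a note for constant traces).
#' The fraction of frames where all traces are simultaneously in contact is
#' attached as attribute `all_contact_fraction` — for the aromatic-cluster
#' pairs this quantifies how rarely all three residues cluster at once.
#'
#' @param series A `distance_series` with >= 2 distance columns.
#' @param cutoff_A Contact cutoff (Angstrom).
#' @return Tibble: `pair_a`, `pair_b`, `co_fraction`, `independent_fraction`,
#'   `correlation`, `note`.
#' @export
contact_cooccurrence <- function(series, cutoff_A = 20) {
  series_tbl <- as_tibble(series)
  dcols <- distance_cols(series_tbl)
  if (length(dcols) < 2) abort("need at least 2 distance traces")
  contact <- purrr::map(series_tbl[dcols], ~ .x < cutoff_A)
  marg <- vapply(contact, mean, numeric(1))
  combos <- utils::combn(dcols, 2, simplify = FALSE)
  out <- purrr::map_dfr(combos, function(cb) {
    a <- series_tbl[[cb[1]]]; b <- series_tbl[[cb[2]]]
    const <- stats::sd(a) == 0 || stats::sd(b) == 0
    tibble(
      pair_a = stringr::str_remove(cb[1], "^d_"),
      pair_b = stringr::str_remove(cb[2], "^d_"),
      co_fraction = mean(contact[[cb[1]]] & contact[[cb[2]]]),
      independent_fraction = marg[[cb[1]]] * marg[[cb[2]]],
      correlation = if (const) NA_real_ else cor(a, b),
      note = if (const) "constant trace: correlation undefined" else NA_character_
    )
  })
  attr(out, "all_contact_fraction") <- mean(Reduce(`&`, contact))
  attr(out, "marginal_fractions") <- setNames(marg, stringr::str_remove(dcols, "^d_"))
  out
}
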