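# Global 1:1 fast-exchange dissociation-constant fitting across residues,
# with Monte-Carlo uncertainty propagating ligand-concentration and
# peak-position errors.

#' Peak position uncertainty from line width and signal-to-noise
#'
#' The position uncertainty of a resonance is its line width divided by the
#' signal-to-noise ratio.
#'
#' @param linewidth_hz Line width (Hz, > 0); vectorised.
#' @param snr Signal-to-noise ratio (> 0); vectorised.
#' @return Position uncertainty (Hz).
#' @examples
#' peak_position_error(20, 50) # 0.4 Hz
#' @export
peak_position_error <- function(linewidth_hz, snr) {
  if (any(!is.finite(linewidth_hz)) || any(linewidth_hz <= 0)) {
    abort("`linewidth_hz` must be finite and > 0")
  }
  if (any(!is.finite(snr)) || any(snr <= 0)) abort("`snr` must be finite and > 0")
  linewidth_hz / snr
}

#' Select residues for global fitting
#'
#' Applies the endpoint significance screen: the perturbation between the
#' first and last ladder points must strictly exceed both the resolution
#' floor and the `mean + 2 sigma` threshold in the fitted dimension
#' ([flag_significant()]), and the residue must have a complete trajectory
#' (no missing points).
#'
#' @param series A `titration_series`.
#' @param dim Dimension to screen and fit (`"H"` or `"N"`).
#' @param resolution_h_hz,resolution_n_hz Resolution floors (Hz).
#' @return Character vector of residue labels. Errors if none qualify;
#'   warns if exactly one does (a single-residue "global" fit).
#' @export
select_fit_residues <- function(series, dim = "H",
                                resolution_h_hz = 2.4, resolution_n_hz = 1.7) {
  dat <- validate_series(series)
  endpoints <- range(dat$point)
  wide <- dat %>%
    filter(.data$point %in% endpoints) %>%
    tidyr::pivot_wider(id_cols = c("residue", "dim"), names_from = "point",
                       names_prefix = "p", values_from = "shift_hz") %>%
    mutate(dd_hz = abs(.data[[paste0("p", endpoints[2])]] -
                         .data[[paste0("p", endpoints[1])]]))
  prof <- wide %>%
    tidyr::pivot_wider(id_cols = "residue", names_from = "dim", values_from = "dd_hz") %>%
    rename(dd_h_hz = "H", dd_n_hz = "N") %>%
    mutate(dd_h_ppm = NA_real_, dd_n_ppm = NA_real_)
  class(prof) <- c("csp_profile", class(prof))
  flagged <- flag_significant(prof, resolution_h_hz, resolution_n_hz)
  sig_col <- if (dim == "H") "sig_h" else "sig_n"
  candidates <- flagged$residue[flagged[[sig_col]]]
  complete <- dat %>%
    filter(.data$dim == !!dim) %>%
    group_by(.data$residue) %>%
    summarise(ok = all(is.finite(.data$shift_hz)) &&
                n() == length(unique(dat$point)), .groups = "drop")
  keep <- intersect(candidates, complete$residue[complete$ok])
  if (length(keep) == 0) abort("no fittable residues: nothing passed the significance screen")
  if (length(keep) == 1) warn("only one significant residue; global fit reduces to a single isotherm")
  sort(keep)
}

# Long-format observations -> points x trajectories matrices (DD: shift
# displacement relative to the first ladder point; W: inverse-variance
# weights, 0 for missing observations).
#' @noRd
series_matrices <- function(dat, residues, dims) {
  dd_tbl <- dat %>%
    filter(.data$dim %in% dims, .data$residue %in% residues) %>%
    group_by(.data$residue, .data$dim) %>%
    arrange(.data$point, .by_group = TRUE) %>%
    mutate(dd = .data$shift_hz - first(.data$shift_hz)) %>%
    ungroup()
  if (nrow(dd_tbl) == 0) abort("no observations for the requested residues/dimensions")
  if (length(unique(dd_tbl$point)) < 4) {
    abort("need at least 4 titration points for a global fit")
  }
  if (max(abs(dd_tbl$dd), na.rm = TRUE) == 0) {
    abort("no signal: all shift displacements are zero")
  }
  points <- sort(unique(dd_tbl$point))
  l_by_point <- dd_tbl %>%
    distinct(.data$point, .data$l_tot_uM) %>%
    arrange(.data$point) %>% pull(.data$l_tot_uM)
  dd_tbl$point_idx <- match(dd_tbl$point, points)
  dd_tbl$trajectory <- paste(dd_tbl$residue, dd_tbl$dim, sep = "/")
  trajs <- sort(unique(dd_tbl$trajectory))
  DD <- matrix(0, length(points), length(trajs), dimnames = list(NULL, trajs))
  W <- matrix(0, length(points), length(trajs))
  idx <- cbind(dd_tbl$point_idx, match(dd_tbl$trajectory, trajs))
  ok_obs <- is.finite(dd_tbl$dd)
  DD[idx[ok_obs, , drop = FALSE]] <- dd_tbl$dd[ok_obs]
  W[idx[ok_obs, , drop = FALSE]] <- 1 / dd_tbl$sigma_hz[ok_obs]^2
  list(DD = DD, W = W, l_by_point = l_by_point, points = points,
       trajs = trajs, dd_tbl = dd_tbl)
}

#' @noRd
validate_series <- function(series) {
  if (!inherits(series, "titration_series")) {
    needed <- c("residue", "point", "l_tot_uM", "dim", "shift_hz", "sigma_hz")
    if (!is.data.frame(series) || !all(needed %in% names(series))) {
      abort("`series` must be a titration_series (see simulate_titration())")
    }
  }
  as_tibble(series)
}

# Profile machinery: for fixed kd the per-trajectory linear parameters
# (baseline offset and amplitude) have closed-form weighted least-squares
# solutions, so chi^2(kd) is evaluated exactly — and, because every
# trajectory shares the bound-fraction vector, simultaneously for all
# trajectories via column sums over a points x trajectories layout. The
# global fit is then a cheap 1-D search in kd.
#' @noRd
profile_solve <- function(f, DD, W, refine_baseline) {
  Wf <- W * f
  S2 <- colSums(Wf * f)
  T1 <- colSums(Wf * DD)
  if (refine_baseline) {
    S0 <- colSums(W)
    S1 <- colSums(Wf)
    T0 <- colSums(W * DD)
    det <- S0 * S2 - S1^2
    ok <- is.finite(det) & det > 0
    dmax <- ifelse(ok, (S0 * T1 - S1 * T0) / det, 0)
    baseline <- ifelse(ok, (S2 * T0 - S1 * T1) / det, 0)
    dmax_var <- ifelse(ok, S0 / det, NA_real_)
  } else {
    ok <- S2 > 0
    dmax <- ifelse(ok, T1 / S2, 0)
    baseline <- rep(0, ncol(DD))
    dmax_var <- ifelse(ok, 1 / S2, NA_real_)
  }
  list(dmax = dmax, baseline = baseline, dmax_var = dmax_var)
}

#' @noRd
profile_chi2 <- function(kd, p_tot, l_by_point, mats, refine_baseline = TRUE) {
  f <- fraction_bound(p_tot, l_by_point, kd)
  sol <- profile_solve(f, mats$DD, mats$W, refine_baseline)
  R <- mats$DD - outer(f, sol$dmax) -
    matrix(sol$baseline, nrow(mats$DD), ncol(mats$DD), byrow = TRUE)
  sum(mats$W * R^2)
}

# Grid-then-refine 1-D search for the chi^2-minimising kd on the matrix
# representation; shared by fit_global_kd() and the Monte-Carlo resampler.
#' @noRd
kd_search <- function(mats, p_tot, l_by_point, kd_grid, refine_baseline) {
  chi_grid <- vapply(kd_grid, profile_chi2, numeric(1),
                     p_tot = p_tot, l_by_point = l_by_point,
                     mats = mats, refine_baseline = refine_baseline)
  imin <- which.min(chi_grid)
  lo <- kd_grid[max(1L, imin - 1L)]
  hi <- kd_grid[min(length(kd_grid), imin + 1L)]
  opt <- optimize(function(lk) {
    profile_chi2(10^lk, p_tot, l_by_point, mats, refine_baseline)
  }, interval = log10(c(lo, hi)), tol = 1e-10)
  list(kd = 10^opt$minimum, chi2 = opt$objective,
       boundary = imin %in% c(1L, length(kd_grid)))
}

#' Global dissociation-constant fit across residues
#'
#' Fits all selected residues' shift trajectories simultaneously to the 1:1
#' fast-exchange model \eqn{\Delta\delta_{r,i} = \Delta\delta_{max,r}\,
#' f_b(L_i; K_d)} with a single shared dissociation constant and one maximum
#' shift change per trajectory (a residue/dimension combination: both the
#' 1H and 15N trajectories of a residue inform the fit by default).
#' Displacements are taken relative to the first (ligand-free) ladder
#' point; because that reference position is measured with the same noise
#' as every other point, each trajectory also carries a small baseline
#' offset that is refined (equivalently: generalised least squares for the
#' shared-reference error). Set `refine_baseline = FALSE` to pin the free
#' position to the first point exactly.
#'
#' Observations are weighted by their inverse squared position
#' uncertainty. The per-trajectory baseline and amplitude enter linearly
#' and are profiled out in closed form, leaving a one-dimensional
#' chi-square in \eqn{K_d}: a log-spaced grid (default 50 points spanning
#' 1e-2 to 1e3 times the protein total) localises the optimum, which is
#' then refined by golden-section search on log10 K_d.
#'
#' @param series A `titration_series`.
#' @param residues Residues to fit (default: [select_fit_residues()]).
#' @param dims Dimensions contributing trajectories (default both).
#' @param refine_baseline Refine a per-trajectory reference offset
#'   (default TRUE).
#' @param kd_grid Optional explicit grid of K_d values (uM).
#' @return A `kd_fit` object: `kd_uM`, asymptotic `kd_se_uM`, per-trajectory
#'   `delta_max` tibble, `residuals` tibble, `convergence` diagnostics.
#' @examples
#' series <- simulate_titration(titration_sim_spec(noise_sd_h_hz = 0,
#'                                                 noise_sd_n_hz = 0))
#' fit <- fit_global_kd(series)
#' glance(fit)
#' @export
fit_global_kd <- function(series, residues = NULL, dims = c("H", "N"),
                          refine_baseline = TRUE, kd_grid = NULL) {
  dat <- validate_series(series)
  p_tot <- attr(series, "p_tot_uM") %||% stop("series lacks p_tot_uM attribute")
  if (is.null(residues)) residues <- select_fit_residues(series, dim = dims[1])
  prep <- series_matrices(dat, residues, dims)
  dd_tbl <- prep$dd_tbl
  l_by_point <- prep$l_by_point
  mats <- list(DD = prep$DD, W = prep$W)
  trajs <- prep$trajs
  if (is.null(kd_grid)) kd_grid <- p_tot * 10^seq(-2, 3, length.out = 50)
  sr <- kd_search(mats, p_tot, l_by_point, kd_grid, refine_baseline)
  if (sr$boundary) {
    warn("grid search minimised at a boundary; the K_d may be outside the searched range")
  }
  kd_hat <- sr$kd
  opt <- list(objective = sr$chi2)
  boundary <- sr$boundary
  # asymptotic SE from the curvature of chi^2 (known-variance weights):
  h <- kd_hat * 1e-4
  d2 <- (profile_chi2(kd_hat + h, p_tot, l_by_point, mats, refine_baseline) -
           2 * opt$objective +
           profile_chi2(kd_hat - h, p_tot, l_by_point, mats, refine_baseline)) / h^2
  kd_se <- if (is.finite(d2) && d2 > 0) sqrt(2 / d2) else NA_real_
  DD <- prep$DD; W <- prep$W
  f_hat <- fraction_bound(p_tot, l_by_point, kd_hat)
  sol <- profile_solve(f_hat, DD, W, refine_baseline)
  traj_parts <- stringr::str_split_fixed(trajs, "/", 2)
  dmax_tbl <- tibble(
    residue = traj_parts[, 1], dim = traj_parts[, 2],
    delta_max_hz = sol$dmax, delta_max_se_hz = sqrt(sol$dmax_var),
    baseline_hz = sol$baseline
  )
  residuals <- dd_tbl %>%
    left_join(dmax_tbl, by = c("residue", "dim")) %>%
    mutate(
      fitted = .data$baseline_hz + .data$delta_max_hz * f_hat[.data$point_idx],
      resid = .data$dd - .data$fitted
    ) %>%
    select("residue", "dim", "point", "l_tot_uM", "dd", "fitted", "resid",
           "sigma_hz")
  n_lin <- length(trajs) * (1L + as.integer(refine_baseline))
  structure(
    list(
      kd_uM = kd_hat, kd_se_uM = kd_se,
      delta_max = dmax_tbl, residuals = residuals,
      residues = sort(unique(dd_tbl$residue)), dims = dims,
      refine_baseline = refine_baseline,
      p_tot_uM = p_tot, l_tot_uM = l_by_point,
      convergence = list(
        chi2 = opt$objective, grid_boundary = boundary,
        n_obs = nrow(dd_tbl),
        df = nrow(dd_tbl) - n_lin - 1L
      )
    ),
    class = "kd_fit"
  )
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf(
    "Global 1:1 K_d fit (%d residues, dimension(s) %s)\n  K_d = %.3g uM (asymptotic SE %.2g)\n  chi2 = %.4g on %d df\n",
    length(x$residues), paste(x$dims, collapse = "+"), x$kd_uM, x$kd_se_uM,
    x$convergence$chi2, x$convergence$df
  ))
  invisible(x)
}

#' @export
tidy.kd_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "kd_uM", estimate = x$kd_uM, std.error = x$kd_se_uM),
    x$delta_max %>%
      mutate(term = paste0("delta_max_hz[", .data$residue, "/", .data$dim, "]")) %>%
      select(term = "term", estimate = "delta_max_hz",
             std.error = "delta_max_se_hz")
  )
}

#' @export
glance.kd_fit <- function(x, ...) {
  tibble(
    kd_uM = x$kd_uM, kd_se_uM = x$kd_se_uM,
    n_residues = length(x$residues), n_obs = x$convergence$n_obs,
    chi2 = x$convergence$chi2, df = x$convergence$df,
    grid_boundary = x$convergence$grid_boundary
  )
}

#' Monte-Carlo uncertainty for the global dissociation constant
#'
#' Replicates the global fit on perturbed pseudo-data: every ligand total is
#' scaled by an independent (or optionally shared) Gaussian factor with 10%
#' coefficient of variation, and every observed position is jittered by its
#' own reported uncertainty. The spread (SD) of replicate estimates is the
#' reported K_d uncertainty.
#'
#' @param series A `titration_series`.
#' @param residues Residues to fit (default: significance screen).
#' @param dims,refine_baseline Passed to [fit_global_kd()].
#' @param n_iter Number of replicates (>= 2; default 500).
#' @param seed RNG seed (mandatory).
#' @param conc_cv Coefficient of variation of the ligand-concentration error
#'   (default 0.10). Set 0 to disable.
#' @param position_noise Jitter observed positions by `sigma_hz`? Default TRUE.
#' @param shared_conc If TRUE, one scale factor per replicate is applied to
#'   the whole ladder instead of per-point factors.
#' @param max_fail_frac Error if more than this fraction of replicates fails
#'   to converge (default 0.2).
#' @return A `kd_mc` object: `kd_sd_uM`, `kd_mean_uM`, replicate table,
#'   failure count.
#' @export
monte_carlo_kd_error <- function(series, residues = NULL, dims = c("H", "N"),
                                 refine_baseline = TRUE,
                                 n_iter = 500, seed, conc_cv = 0.10,
                                 position_noise = TRUE, shared_conc = FALSE,
                                 max_fail_frac = 0.2) {
  if (n_iter < 2) abort("`n_iter` must be at least 2 to form an SD")
  assert_number(conc_cv, "conc_cv", lower = 0)
  dat <- validate_series(series)
  p_tot <- attr(series, "p_tot_uM")
  if (is.null(residues)) residues <- select_fit_residues(series, dim = dims[1])
  prep <- series_matrices(dat, residues, dims)
  kd_grid <- p_tot * 10^seq(-2, 3, length.out = 50)
  # base fit on the unperturbed data; replicate searches start from a
  # one-decade bracket around it (the full grid is only needed cold)
  base <- kd_search(list(DD = prep$DD, W = prep$W), p_tot, prep$l_by_point,
                    kd_grid, refine_baseline)
  mc_grid <- kd_grid[kd_grid >= base$kd / 10 & kd_grid <= base$kd * 10]
  if (length(mc_grid) < 5) mc_grid <- kd_grid
  sigma <- ifelse(prep$W > 0, 1 / sqrt(prep$W), 0)
  np <- nrow(prep$DD); nt <- ncol(prep$DD)
  kds <- with_sim_seed(seed, {
    purrr::map_dbl(seq_len(n_iter), function(i) {
      l_rep <- prep$l_by_point
      if (conc_cv > 0) {
        fac <- if (shared_conc) rnorm(1, 1, conc_cv) else rnorm(np, 1, conc_cv)
        l_rep <- l_rep * pmax(fac, 1e-6)
      }
      DD_rep <- prep$DD
      if (position_noise) {
        # jitter observed positions, then re-reference to the (also
        # jittered) first ladder point, as displacements are defined
        e <- matrix(rnorm(np * nt), np, nt) * sigma
        DD_rep <- DD_rep + e - matrix(e[1, ], np, nt, byrow = TRUE)
      }
      tryCatch(
        kd_search(list(DD = DD_rep, W = prep$W), p_tot, l_rep, mc_grid,
                  refine_baseline)$kd,
        error = function(e) NA_real_
      )
    })
  })
  n_fail <- sum(is.na(kds))
  if (n_fail > max_fail_frac * n_iter) {
    abort(sprintf("%d of %d Monte-Carlo replicates failed to converge", n_fail, n_iter))
  }
  ok <- kds[!is.na(kds)]
  structure(
    list(
      kd_sd_uM = stats::sd(ok), kd_mean_uM = mean(ok),
      replicates = tibble(iter = seq_len(n_iter), kd_uM = kds),
      n_fail = n_fail, n_iter = n_iter,
      conc_cv = conc_cv, position_noise = position_noise
    ),
    class = "kd_mc"
  )
}

#' @export
print.kd_mc <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo K_d uncertainty: SD = %.3g uM over %d replicates (%d failed)\n",
    x$kd_sd_uM, x$n_iter, x$n_fail
  ))
  invisible(x)
}

#' @export
glance.kd_mc <- function(x, ...) {
  tibble(kd_mean_uM = x$kd_mean_uM, kd_sd_uM = x$kd_sd_uM,
         n_iter = x$n_iter, n_fail = x$n_fail)
}
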