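# Displacement and functional-assay analysis: ratiometric free/bound
# populations, anisotropy direct binding, dose-response IC50, and kinase
# activity changes.

#' Free-state population from a free/bound peak doublet
#'
#' For residues showing both a free and a receptor-bound resonance, the
#' relative free population is the free intensity as a fraction of the
#' doublet total: `p_free = I_free / (I_free + I_bound)`. Invariant to
#' global intensity rescaling.
#'
#' @param doublets Tibble with columns `I_free` and `I_bound` (plus any
#'   identifiers, preserved).
#' @return The input with `p_free` and `p_bound` columns added.
#' @examples
#' free_population(tibble::tibble(residue = "62", I_free = 30, I_bound = 70))
#' @export
free_population <- function(doublets) {
  doublets <- as_tibble(doublets)
  if (!all(c("I_free", "I_bound") %in% names(doublets))) {
    abort("`doublets` needs columns I_free and I_bound")
  }
  if (any(doublets$I_free < 0) || any(doublets$I_bound < 0)) {
    abort("intensities must be non-negative")
  }
  tot <- doublets$I_free + doublets$I_bound
  if (any(tot == 0)) {
    abort(sprintf("doublet with zero total intensity at row %s",
                  paste(which(tot == 0), collapse = ", ")))
  }
  doublets %>%
    mutate(p_free = .data$I_free / tot, p_bound = 1 - .data$p_free)
}

#' Build a displacement profile from doublets in two conditions
#'
#' Aggregates replicate free-population measurements without and with the
#' compound, then forms per-residue ratios `r_free = p_free(with) /
#' p_free(without)` and `r_bound = p_bound(with) / p_bound(without)` with
#' uncertainties propagated from the replicate SDs (first-order ratio
#' propagation). A free-state ratio above 1 together with a bound-state
#' ratio below 1 is the displacement signature.
#'
#' @param doublets Tibble with columns `residue`, `condition` (`"without"` /
#'   `"with"`), `replicate`, `I_free`, `I_bound` (see
#'   [simulate_displacement()] for the layout).
#' @return A `displacement_profile` tibble: per residue, mean and SD of
#'   `p_free` in each condition plus `r_free`, `r_free_sd`, `r_bound`,
#'   `r_bound_sd`. Residues lacking either condition are dropped with a
#'   message.
#' @export
displacement_profile <- function(doublets) {
  doublets <- as_tibble(doublets)
  needed <- c("residue", "condition", "I_free", "I_bound")
  if (!all(needed %in% names(doublets))) {
    abort(paste0("`doublets` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (!all(doublets$condition %in% c("without", "with"))) {
    abort("`condition` must be 'without' or 'with'")
  }
  pops <- free_population(doublets)
  agg <- pops %>%
    group_by(.data$residue, .data$condition) %>%
    summarise(
      p_free_mean = mean(.data$p_free),
      p_free_sd = ifelse(n() > 1, stats::sd(.data$p_free), 0),
      n_rep = n(), .groups = "drop"
    )
  wide <- agg %>%
    tidyr::pivot_wider(id_cols = "residue", names_from = "condition",
                       values_from = c("p_free_mean", "p_free_sd", "n_rep"))
  incomplete <- wide %>%
    filter(is.na(.data$p_free_mean_without) | is.na(.data$p_free_mean_with))
  if (nrow(incomplete) > 0) {
    inform(paste0("residues missing a condition were skipped: ",
                  paste(incomplete$residue, collapse = ", ")))
    wide <- anti_join(wide, incomplete, by = "residue")
  }
  ratio_sd <- function(a, sa, b, sb) {
    abs(a / b) * sqrt((sa / a)^2 + (sb / b)^2)
  }
  out <- wide %>%
    mutate(
      p_bound_mean_without = 1 - .data$p_free_mean_without,
      p_bound_mean_with = 1 - .data$p_free_mean_with,
      r_free = .data$p_free_mean_with / .data$p_free_mean_without,
      r_free_sd = ratio_sd(.data$p_free_mean_with, .data$p_free_sd_with,
                           .data$p_free_mean_without, .data$p_free_sd_without),
      r_bound = .data$p_bound_mean_with / .data$p_bound_mean_without,
      r_bound_sd = ratio_sd(.data$p_bound_mean_with, .data$p_free_sd_with,
                            .data$p_bound_mean_without, .data$p_free_sd_without)
    )
  class(out) <- c("displacement_profile", class(out))
  out
}

#' Per-residue displacement verdicts
#'
#' A residue is called `displaced` when the free-state ratio exceeds 1 and
#' the bound-state ratio falls below 1, each by more than `n_sd` propagated
#' replicate SDs. Ratios that sit exactly at 1 (no change) give
#' `not_displaced`; anything whose deviation from 1 is within its error is
#' `indeterminate`.
#'
#' @param profile A [displacement_profile()], or a tibble with columns
#'   `residue`, `r_free`, `r_free_sd`, `r_bound`, `r_bound_sd`.
#' @param n_sd Number of SDs an inequality must clear (default 1).
#' @return The profile with a `verdict` column.
#' @export
displacement_call <- function(profile, n_sd = 1) {
  profile <- as_tibble(profile)
  needed <- c("residue", "r_free", "r_free_sd", "r_bound", "r_bound_sd")
  if (!all(needed %in% names(profile))) {
    abort(paste0("`profile` needs columns: ", paste(needed, collapse = ", ")))
  }
  eps <- 1e-12
  dev_f <- profile$r_free - 1
  dev_b <- profile$r_bound - 1
  sig_f <- abs(dev_f) > n_sd * profile$r_free_sd
  sig_b <- abs(dev_b) > n_sd * profile$r_bound_sd
  verdict <- dplyr::case_when(
    sig_f & dev_f > 0 & sig_b & dev_b < 0 ~ "displaced",
    abs(dev_f) < eps & abs(dev_b) < eps ~ "not_displaced",
    (sig_f & dev_f < 0) & (sig_b & dev_b > 0) ~ "not_displaced",
    TRUE ~ "indeterminate"
  )
  profile %>% mutate(verdict = verdict)
}

#' Fit a direct-binding anisotropy isotherm
#'
#' Fits `r = r_free + (r_bound - r_free) * f_b(L; K_d)` with the bound
#' fraction from the exact 1:1 depletion quadratic ([fraction_bound()]), the
#' probe held at its fixed total. Weighted (1/sd^2 where replicate SDs are
#' positive) Levenberg-Marquardt least squares.
#'
#' @param series Tibble with columns `conc`, `response` and optionally `sd`
#'   (e.g. from [simulate_anisotropy()]).
#' @param probe_tot Probe total concentration in the same unit as `conc`
#'   (default: the series' `probe_tot` attribute).
#' @return An `fa_fit`: `kd`, `kd_se`, `r_free`, `r_bound`, fitted values.
#'   Warns when the ladder does not approach saturation (max conc < 5 K_d),
#'   in which case the K_d is poorly bounded above.
#' @export
fit_direct_binding <- function(series, probe_tot = NULL) {
  series <- as_tibble(series)
  if (!all(c("conc", "response") %in% names(series))) {
    abort("`series` needs columns conc and response")
  }
  if (nrow(series) < 5) abort("need at least 5 titration points")
  probe_tot <- probe_tot %||% attr(series, "probe_tot")
  if (is.null(probe_tot)) abort("supply `probe_tot` (same unit as conc)")
  r0 <- series$response[which.min(series$conc)]
  r1 <- series$response[which.max(series$conc)]
  half <- (r0 + r1) / 2
  kd0 <- stats::approx(series$response, series$conc, xout = half, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(series$conc[series$conc > 0])
  wts <- if ("sd" %in% names(series) && all(series$sd > 0)) 1 / series$sd^2 else
    rep(1, nrow(series))
  fit <- minpack.lm::nlsLM(
    response ~ r_free + (r_bound - r_free) * fraction_bound(probe_tot, conc, kd),
    data = series,
    start = list(r_free = r0, r_bound = r1, kd = kd0),
    weights = wts,
    lower = c(r_free = -Inf, r_bound = -Inf, kd = .Machine$double.eps),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (max(series$conc) < 5 * est[["kd"]]) {
    warn("ladder does not approach saturation; K_d uncertainty is understated above")
  }
  structure(
    list(
      kd = est[["kd"]], kd_se = se[["kd"]],
      r_free = est[["r_free"]], r_bound = est[["r_bound"]],
      probe_tot = probe_tot,
      data = series %>% mutate(fitted = stats::fitted(fit),
                               resid = stats::resid(fit)),
      fit = fit
    ),
    class = "fa_fit"
  )
}

#' @export
print.fa_fit <- function(x, ...) {
  cat(sprintf("Direct-binding anisotropy fit\n  K_d = %.4g (SE %.2g), r_free = %.4g, r_bound = %.4g\n",
              x$kd, x$kd_se, x$r_free, x$r_bound))
  invisible(x)
}

#' @export
tidy.fa_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @export
glance.fa_fit <- function(x, ...) {
  tibble(kd = x$kd, kd_se = x$kd_se, r_free = x$r_free, r_bound = x$r_bound,
         n = nrow(x$data))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `response = bottom + (top - bottom) / (1 + (conc/ic50)^hill)` by
#' Levenberg-Marquardt least squares with asymptotic uncertainties. When
#' replicate rows share a dose they are first averaged (curve fitting on the
#' replicate average). A warning is raised when the dose-response trend is
#' not monotone beyond noise (|Kendall tau| < 0.5).
#'
#' @param series Tibble with `conc` (> 0) and `response`; or supply two
#'   vectors via `conc`/`response` arguments.
#' @param conc,response Alternative vector interface.
#' @param fix_top,fix_bottom Optional fixed asymptotes.
#' @return An `ic50_fit`: `ic50`, `ic50_se`, `hill`, `top`, `bottom`,
#'   fitted values and residuals.
#' @export
fit_ic50 <- function(series = NULL, conc = NULL, response = NULL,
                     fix_top = NULL, fix_bottom = NULL) {
  if (is.null(series)) series <- tibble(conc = conc, response = response)
  series <- as_tibble(series)
  if (!all(c("conc", "response") %in% names(series))) {
    abort("`series` needs columns conc and response")
  }
  if (any(series$conc <= 0)) abort("doses must be > 0 for a logistic fit")
  avg <- series %>%
    group_by(.data$conc) %>%
    summarise(response = mean(.data$response), .groups = "drop") %>%
    arrange(.data$conc)
  if (nrow(avg) < 5) abort("need at least 5 distinct doses")
  tau <- suppressWarnings(cor(avg$conc, avg$response, method = "kendall"))
  if (is.na(tau) || abs(tau) < 0.5) {
    warn("dose-response trend is not monotone beyond noise; fit may be unreliable")
  }
  decreasing <- tau < 0
  top0 <- fix_top %||% if (decreasing) max(avg$response) else min(avg$response)
  bot0 <- fix_bottom %||% if (decreasing) min(avg$response) else max(avg$response)
  half <- (top0 + bot0) / 2
  ic0 <- stats::approx(avg$response, avg$conc, xout = half, ties = mean)$y
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- exp(mean(log(range(avg$conc))))
  free <- c(ic50 = unname(ic0), hill = 1)
  start <- as.list(free)
  if (is.null(fix_top)) start$top <- top0
  if (is.null(fix_bottom)) start$bottom <- bot0
  form_top <- if (is.null(fix_top)) "top" else format(fix_top)
  form_bot <- if (is.null(fix_bottom)) "bottom" else format(fix_bottom)
  formula <- stats::as.formula(sprintf(
    "response ~ %s + (%s - %s) / (1 + (conc/ic50)^hill)",
    form_bot, form_top, form_bot
  ))
  lower <- rep(-Inf, length(start)); names(lower) <- names(start)
  lower["ic50"] <- .Machine$double.eps
  fit <- minpack.lm::nlsLM(formula, data = avg, start = start, lower = lower,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(
    list(
      ic50 = est[["ic50"]], ic50_se = se[["ic50"]],
      hill = est[["hill"]],
      top = if (is.null(fix_top)) est[["top"]] else fix_top,
      bottom = if (is.null(fix_bottom)) est[["bottom"]] else fix_bottom,
      data = avg %>% mutate(fitted = stats::fitted(fit),
                            resid = stats::resid(fit)),
      fit = fit
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf(
    "Four-parameter logistic fit\n  IC50 = %.4g (SE %.2g), hill = %.3g, top = %.4g, bottom = %.4g\n",
    x$ic50, x$ic50_se, x$hill, x$top, x$bottom
  ))
  invisible(x)
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, ic50_se = x$ic50_se, hill = x$hill,
         top = x$top, bottom = x$bottom, n = nrow(x$data))
}

#' Relative activity change between conditions
#'
#' Computes the relative change of each treated activity against a baseline,
#' `100 * (treated - baseline) / baseline` (percent of baseline), and
#' classifies the direction: activation (> 0), inhibition (< 0) or none.
#' Useful for, e.g., quantifying partial restoration of kinase activity upon
#' inhibitor displacement.
#'
#' @param baseline Baseline activity (percent of uninhibited activity; != 0).
#' @param treated Named or unnamed numeric vector of treated activities on
#'   the same scale.
#' @return Tibble: `condition`, `activity`, `relative_change_pct`, `class`.
#' @examples
#' activity_analysis(13, c(with_compound = 20))
#' @export
activity_analysis <- function(baseline, treated) {
  assert_number(baseline, "baseline")
  if (baseline == 0) abort("baseline activity must be non-zero")
  if (!is.numeric(treated) || length(treated) < 1) {
    abort("`treated` must be a numeric vector")
  }
  nms <- names(treated) %||% paste0("condition", seq_along(treated))
  nms[nms == ""] <- paste0("condition", which(nms == ""))
  rel <- 100 * (treated - baseline) / baseline
  tibble(
    condition = nms, activity = unname(treated),
    relative_change_pct = unname(rel),
    class = case_when(rel > 0 ~ "activation", rel < 0 ~ "inhibition",
                      TRUE ~ "none")
  )
}
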