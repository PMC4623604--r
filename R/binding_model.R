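#' Fraction of protein bound under 1:1 ligand depletion
#'
#' Solves the exact 1:1 mass-balance ("ligand depletion") quadratic for the
#' complex concentration and returns the bound fraction of the observed
#' species. Unlike the hyperbolic approximation, this remains correct when
#' the ligand is not in large excess over the protein.
#'
#' With totals \eqn{P} (observed species), \eqn{L} (titrant) and dissociation
#' constant \eqn{K_d}, the complex concentration is
#' \deqn{[PL] = \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2}}
#' and the bound fraction is \eqn{[PL]/P}. The implementation uses the
#' numerically stable conjugate form \eqn{2PL / (s + \sqrt{s^2 - 4PL})} so
#' small bound fractions do not suffer cancellation.
#'
#' @param p_tot Total concentration of the observed species. Any concentration
#'   unit, as long as all three arguments share it.
#' @param l_tot Total titrant concentration(s); vectorised.
#' @param kd Dissociation constant, same unit, strictly positive.
#' @return Numeric vector of bound fractions in \[0, 1\], one per `l_tot`.
#' @examples
#' fraction_bound(100, c(0, 300, 3000), kd = 2200)
#' @export
fraction_bound <- function(p_tot, l_tot, kd) {
  if (!is.numeric(p_tot) || !is.numeric(l_tot) || !is.numeric(kd)) {
    abort("`p_tot`, `l_tot` and `kd` must be numeric")
  }
  if (any(is.na(c(p_tot, l_tot, kd)))) abort("concentrations must not be NA")
  if (any(kd <= 0)) abort("`kd` must be strictly positive")
  if (any(p_tot < 0) || any(l_tot < 0)) abort("concentrations must be non-negative")
  n <- max(length(p_tot), length(l_tot), length(kd))
  p <- rep_len(p_tot, n); l <- rep_len(l_tot, n); k <- rep_len(kd, n)
  s <- p + l + k
  disc <- pmax(s^2 - 4 * p * l, 0)
  pl <- 2 * p * l / (s + sqrt(disc))
  f <- ifelse(p > 0, pl / p, 0)
  pmin(pmax(f, 0), 1)
}

#' Solve a ternary competition equilibrium
#'
#' Solves the coupled mass-action equilibria of a competition experiment in
#' which a ligand displaces a probe from its receptor:
#' \eqn{C + D \rightleftharpoons CD} (`kd_cd`),
#' \eqn{D + L \rightleftharpoons DL} (`kd_dl`) and optionally
#' \eqn{C + L \rightleftharpoons CL} (`kd_cl`). Here `D` is the shared
#' species (for a displacement assay: the labelled probe domain), `C` the
#' receptor and `L` the competing small molecule. All equilibria are
#' parameterised by dissociation constants.
#'
#' The solver iterates damped fixed-point updates of the free concentrations
#' until every mass balance closes to `tol` times the largest total, and
#' errors if convergence is not reached.
#'
#' @param c_tot,d_tot,l_tot Total concentrations (any shared unit, >= 0).
#' @param kd_cd,kd_dl Dissociation constants of the C-D and D-L equilibria.
#' @param kd_cl Optional dissociation constant for direct C-L binding;
#'   `NULL` (default) omits that equilibrium.
#' @param tol Relative mass-balance tolerance (default 1e-10).
#' @param max_iter Iteration cap.
#' @return One-row tibble with free concentrations (`c_free`, `d_free`,
#'   `l_free`), complexes (`cd`, `dl`, `cl`), the bound fraction of D on C
#'   (`f_d_bound`), the worst relative mass-balance residual and the
#'   iteration count.
#' @examples
#' # probe D (20 nM) on receptor C (300 nM), no competitor
#' solve_ternary(300, 20, 0, kd_cd = 73, kd_dl = 2.2e6)
#' @export
solve_ternary <- function(c_tot, d_tot, l_tot, kd_cd, kd_dl, kd_cl = NULL,
                          tol = 1e-10, max_iter = 50000L) {
  for (nm in c("c_tot", "d_tot", "l_tot")) assert_number(get(nm), nm, lower = 0)
  assert_number(kd_cd, "kd_cd", lower = 0, strict = TRUE)
  assert_number(kd_dl, "kd_dl", lower = 0, strict = TRUE)
  if (!is.null(kd_cl)) assert_number(kd_cl, "kd_cl", lower = 0, strict = TRUE)
  scale <- max(c_tot, d_tot, l_tot)
  if (scale == 0) {
    return(tibble(
      c_free = 0, d_free = 0, l_free = 0, cd = 0, dl = 0, cl = 0,
      f_d_bound = 0, residual = 0, iterations = 0L
    ))
  }
  has_cl <- !is.null(kd_cl)
  cf <- c_tot; df <- d_tot; lf <- l_tot
  damp <- 0.5
  resid <- Inf
  for (it in seq_len(max_iter)) {
    cl_term_c <- if (has_cl) lf / kd_cl else 0
    cl_term_l <- if (has_cl) cf / kd_cl else 0
    cf_new <- c_tot / (1 + df / kd_cd + cl_term_c)
    df_new <- d_tot / (1 + cf / kd_cd + lf / kd_dl)
    lf_new <- l_tot / (1 + df / kd_dl + cl_term_l)
    cf <- (1 - damp) * cf + damp * cf_new
    df <- (1 - damp) * df + damp * df_new
    lf <- (1 - damp) * lf + damp * lf_new
    cd <- cf * df / kd_cd
    dl <- df * lf / kd_dl
    cl <- if (has_cl) cf * lf / kd_cl else 0
    resid <- max(
      abs(cf + cd + cl - c_tot),
      abs(df + cd + dl - d_tot),
      abs(lf + dl + cl - l_tot)
    ) / scale
    if (resid < tol) break
  }
  if (resid >= tol) {
    abort(sprintf(
      "ternary solver did not converge in %d iterations (relative residual %.3e)",
      max_iter, resid
    ))
  }
  tibble(
    c_free = cf, d_free = df, l_free = lf, cd = cd, dl = dl, cl = cl,
    f_d_bound = if (d_tot > 0) cd / d_tot else 0,
    residual = resid, iterations = it
  )
}

#' Predict a displacement IC50 from a ternary competition model
#'
#' Computes the competitor concentration at which the receptor-bound fraction
#' of the probe falls halfway between its value without competitor and its
#' fully displaced floor, under the mass-action competition model of
#' [solve_ternary()]. Useful to compare a mechanistic prediction (probe
#' displacement purely through competitor binding to the probe) with a
#' measured IC50.
#'
#' @inheritParams solve_ternary
#' @param interval Search interval for the competitor total (same unit).
#' @return Predicted IC50 (scalar) in the concentration unit of the inputs.
#' @export
predict_displacement_ic50 <- function(c_tot, d_tot, kd_cd, kd_dl, kd_cl = NULL,
                                      interval = c(1e-3, 1e12)) {
  f0 <- solve_ternary(c_tot, d_tot, 0, kd_cd, kd_dl, kd_cl)$f_d_bound
  f_inf <- solve_ternary(c_tot, d_tot, interval[2], kd_cd, kd_dl, kd_cl)$f_d_bound
  if (f0 <= f_inf + 1e-12) abort("competitor cannot displace the probe in this model")
  target <- (f0 + f_inf) / 2
  root <- uniroot(
    function(l) solve_ternary(c_tot, d_tot, l, kd_cd, kd_dl, kd_cl)$f_d_bound - target,
    interval = interval, tol = 1e-6 * interval[2]
  )
  root$root
}
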