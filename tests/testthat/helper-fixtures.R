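# Shared fixtures and independent oracles, built in code at test time.

# A minimal backbone peak list at a given field; dH/dN supplied per residue.
make_peak_list <- function(dh_ppm, dn_ppm = rep(110, length(dh_ppm)),
                           residues = as.character(seq_along(dh_ppm)),
                           field_MHz = 800, lw_h = 20, lw_n = 15, snr = 50) {
  peak_list(
    tibble::tibble(
      residue = residues, dH_ppm = dh_ppm, dN_ppm = dn_ppm,
      intensity = 1, lw_H_hz = lw_h, lw_N_hz = lw_n, snr = snr
    ),
    field_MHz = field_MHz
  )
}

# A hand-made flagged profile with significant residues at `sig_at`.
make_flagged_profile <- function(sig_at) {
  p <- tibble::tibble(
    residue = as.character(sig_at),
    dd_h_ppm = 0.05, dd_h_hz = 40, dd_n_ppm = 0.005, dd_n_hz = 4,
    sig_h = TRUE, sig_n = FALSE
  )
  class(p) <- c("csp_profile", class(p))
  p
}

# Independent oracle for the 1:1 depletion bound fraction: bisection on the
# mass-balance residual, no closed form shared with the implementation.
oracle_fraction_bound <- function(p, l, kd, tol = 1e-12) {
  if (p == 0) return(0)
  resid <- function(pl) (p - pl) * (l - pl) - kd * pl
  lo <- 0; hi <- min(p, l)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / p
}

# Write a small multi-model PDB with CB atoms for the three aromatic
# residues; coords is a list of frames, each a named list of xyz triples.
write_test_pdb <- function(coords, path) {
  resno <- c(W60 = 60, W76 = 76, Y88 = 88)
  resnm <- c(W60 = "TRP", W76 = "TRP", Y88 = "TYR")
  lines <- character(0)
  for (m in seq_along(coords)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    i <- 0
    for (nm in names(coords[[m]])) {
      i <- i + 1
      xyz <- coords[[m]][[nm]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  CB  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, resnm[[nm]], resno[[nm]], xyz[1], xyz[2], xyz[3]
      ))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
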