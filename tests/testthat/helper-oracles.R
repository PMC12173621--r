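# Independent oracles used across the suite. These deliberately take the
# long way round (full 3D tensor relation, explicit enumeration, raw sums
# of squares) so they share no code path with the implementation.

# Piola stresses from the full three-dimensional relation
# P = dpsi/dF - p F^-T for diagonal F = diag(f1, f2, f3), f3 = 1/(f1 f2),
# with dpsi/dF by central finite differences of psi(I1(F), I2(F)) treated
# as a free function of the three diagonal components, and the pressure p
# fixed by P33 = 0.
fd_piola_oracle <- function(model, lambda1, lambda2, h = 1e-6) {
  f <- c(lambda1, lambda2, 1 / (lambda1 * lambda2))
  psiF <- function(f) {
    I1 <- sum(f^2)
    I2 <- f[1]^2 * f[2]^2 + f[1]^2 * f[3]^2 + f[2]^2 * f[3]^2
    model$psi(I1, I2)
  }
  dpsi <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h * f[i]
    (psiF(f + e) - psiF(f - e)) / (2 * h * f[i])
  }, numeric(1))
  p <- f[3] * dpsi[3]                      # from P33 = dpsi/df3 - p/f3 = 0
  list(P11 = dpsi[1] - p / f[1],
       P22 = dpsi[2] - p / f[2],
       P33 = dpsi[3] - p / f[3])
}

# Exact two-sided Spearman permutation p-value by naive recursive
# enumeration (usable up to n = 7), computing the coefficient per
# permutation with cor() on midranks.
spearman_p_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rhos <- vapply(perms(ry), function(p) cor(rx, p), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# One-way ANOVA F by raw sums of squares.
anova_f_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Long-format biax_data built directly from a closed-form model over the
# standard five-mode stretch grid (no recordings involved).
closed_form_dataset <- function(c1, c2 = 0, max_stretch = 1.1,
                                n_points = 11) {
  lead <- seq(1, max_stretch, length.out = n_points)
  rows <- list()
  for (m in biaxial_modes()) {
    path <- switch(m,
                   "strip-x" = list(l1 = lead, l2 = rep(1, n_points)),
                   "strip-y" = list(l1 = rep(1, n_points), l2 = lead),
                   "equibiax" = list(l1 = lead, l2 = lead),
                   "off-x" = list(l1 = lead, l2 = sqrt(lead)),
                   "off-y" = list(l1 = sqrt(lead), l2 = lead))
    p <- mr_stress(c1, c2, path$l1, path$l2)
    rows[[length(rows) + 1]] <- data.frame(
      mode = m, direction = "x", stretch = path$l1, stress_kPa = p$P11)
    rows[[length(rows) + 1]] <- data.frame(
      mode = m, direction = "y", stretch = path$l2, stress_kPa = p$P22)
  }
  as_biax_data(do.call(rbind, rows))
}

# A clean triangular-cycle recording (no preload phase) for cycle tests.
triangle_recording <- function(cycles = 3, mode = "equibiax", L = 12,
                               thickness = 1, peak = 1.1, n_ramp = 20) {
  up <- seq(1, peak, length.out = n_ramp + 1)
  lead <- 1
  for (k in seq_len(cycles)) lead <- c(lead, up[-1], rev(up)[-1])
  path <- switch(mode,
                 "equibiax" = list(l1 = lead, l2 = lead),
                 "strip-x" = list(l1 = lead, l2 = rep(1, length(lead))),
                 stop("unsupported mode in helper"))
  p <- nh_stress(50, path$l1, path$l2)
  biaxial_recording(time = seq_along(lead),
                    force_x = p$P11 * L * thickness,
                    force_y = p$P22 * L * thickness,
                    gauge_x = path$l1 * L, gauge_y = path$l2 * L,
                    thickness = thickness, mode = mode)
}
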