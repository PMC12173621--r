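# Eight-term invariant-based constitutive network: energy evaluation,
# Adam training with L1 sparsity on non-negative weights, and automated
# two-term model selection.

.CANN_TERMS <- c("I1 linear", "I1 exponential", "I1 quadratic",
                 "I1 exp-quadratic", "I2 linear", "I2 exponential",
                 "I2 quadratic", "I2 exp-quadratic")
.EXP_GUARD <- 50  # exponent bound before the energy is declared overflowed

#' Term labels of the discovery network
#'
#' The network's strain energy is a sum of eight decoupled terms: linear,
#' exponential, quadratic and exponential-quadratic functions of `(I1 - 3)`
#' (terms 1-4) and of `(I2 - 3)` (terms 5-8),
#' \deqn{\psi = w_1 w_1^*(I_1-3) + w_2[e^{w_2^*(I_1-3)}-1]
#'  + w_3 w_3^*(I_1-3)^2 + w_4[e^{w_4^*(I_1-3)^2}-1] + \ldots}
#' with the same four shapes in `I2` carried by weights 5-8. Each term has
#' an external weight `w` (kPa scale) and an internal dimensionless weight
#' `w*`. Term 1 alone is the neo-Hookean model (`c1 = 2 w1 w1*`); terms
#' `{1, 5}` embed the Mooney-Rivlin model.
#'
#' @return Character vector of the eight term labels.
#' @export
cann_terms <- function() .CANN_TERMS

check_cann_weights <- function(w, ws) {
  stopifnot(is.numeric(w), length(w) == 8, is.numeric(ws), length(ws) == 8)
  if (any(!is.finite(w)) || any(!is.finite(ws)))
    stop("network weights must be finite", call. = FALSE)
  if (any(w < 0) || any(ws < 0))
    stop("network weights must be non-negative", call. = FALSE)
  invisible(NULL)
}

# exponent guard: x, ws scalars/vectors; term label for the error message
guarded_exp <- function(arg, term) {
  if (any(arg > .EXP_GUARD))
    stop("overflow in exponential of term '", term,
         "' (exponent > ", .EXP_GUARD, ")", call. = FALSE)
  exp(arg)
}

#' Network strain energy and its derivatives
#'
#' `cann_energy()` evaluates the eight-term energy at given invariants;
#' `energy_cann()` wraps a weight set as an [energy_model()], so network
#' predictions flow through the same [piola_biaxial()] kinematics as the
#' classical models. `cann_stress()` is the direct stress shortcut.
#'
#' @param w,ws external (kPa) and internal (dimensionless) weights, length
#'   8 each, non-negative.
#' @param I1,I2 invariants (vectorized).
#' @return `cann_energy()`: energy density in kPa; `energy_cann()`: an
#'   [energy_model()]; `cann_stress()`: list with `P11`, `P22`.
#' @export
cann_energy <- function(w, ws, I1, I2) {
  check_cann_weights(w, ws)
  x <- I1 - 3; y <- I2 - 3
  w[1] * ws[1] * x + w[2] * (guarded_exp(ws[2] * x, .CANN_TERMS[2]) - 1) +
    w[3] * ws[3] * x^2 +
    w[4] * (guarded_exp(ws[4] * x^2, .CANN_TERMS[4]) - 1) +
    w[5] * ws[5] * y + w[6] * (guarded_exp(ws[6] * y, .CANN_TERMS[6]) - 1) +
    w[7] * ws[7] * y^2 +
    w[8] * (guarded_exp(ws[8] * y^2, .CANN_TERMS[8]) - 1)
}

cann_dI1 <- function(w, ws, I1) {
  x <- I1 - 3
  w[1] * ws[1] + w[2] * ws[2] * guarded_exp(ws[2] * x, .CANN_TERMS[2]) +
    2 * w[3] * ws[3] * x +
    2 * w[4] * ws[4] * x * guarded_exp(ws[4] * x^2, .CANN_TERMS[4])
}

cann_dI2 <- function(w, ws, I2) {
  y <- I2 - 3
  w[5] * ws[5] + w[6] * ws[6] * guarded_exp(ws[6] * y, .CANN_TERMS[6]) +
    2 * w[7] * ws[7] * y +
    2 * w[8] * ws[8] * y * guarded_exp(ws[8] * y^2, .CANN_TERMS[8])
}

#' @rdname cann_energy
#' @export
energy_cann <- function(w, ws) {
  check_cann_weights(w, ws)
  force(w); force(ws)
  energy_model(
    psi = function(I1, I2) cann_energy(w, ws, I1, I2),
    dI1 = function(I1, I2) rep_len(cann_dI1(w, ws, I1), length(I1)),
    dI2 = function(I1, I2) rep_len(cann_dI2(w, ws, I2), length(I2)),
    name = "constitutive network",
    parameters = list(w = w, ws = ws))
}

#' @rdname cann_energy
#' @param lambda1,lambda2 in-plane stretches.
#' @export
cann_stress <- function(w, ws, lambda1, lambda2) {
  piola_biaxial(energy_cann(w, ws), lambda1, lambda2)
}

#' Training configuration for the discovery network
#'
#' @param learning_rate Adam step size.
#' @param epochs maximum gradient steps.
#' @param l1_alpha L1 penalty weight used by [train_cann()] when no sweep is
#'   run.
#' @param alpha_sweep ascending penalty grid for [discover_model()].
#' @param zero_threshold a term counts as active when its weight product
#'   `w * w*` exceeds this fraction of the largest product.
#' @param seed RNG seed for the uniform(0, 1) weight initialization.
#' @param refit refit the selected terms without penalty after selection.
#' @param penalize_internal also place the L1 penalty on the internal
#'   (dimensionless) weights; by default only the kPa-scale external
#'   weights are penalized so the penalty has a single unit.
#' @param tol relative loss-change tolerance for early stopping, checked
#'   every 100 epochs over a 500-epoch window.
#' @return List of class `cann_control`.
#' @export
cann_control <- function(learning_rate = 1e-3, epochs = 20000,
                         l1_alpha = 0, alpha_sweep = 10^seq(-4, 0, by = 0.5),
                         zero_threshold = 1e-3, seed = 1, refit = TRUE,
                         penalize_internal = FALSE, tol = 1e-8) {
  stopifnot(learning_rate > 0, epochs >= 1, l1_alpha >= 0,
            all(alpha_sweep >= 0), zero_threshold >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 l1_alpha = l1_alpha, alpha_sweep = sort(alpha_sweep),
                 zero_threshold = zero_threshold, seed = seed,
                 refit = refit, penalize_internal = penalize_internal,
                 tol = tol),
            class = "cann_control")
}

# Precompute everything the gradient loop needs from a states table.
cann_problem <- function(states) {
  inv <- invariants(states$l1, states$l2)
  f <- biax_factors(states$l1, states$l2)
  list(x = inv$I1 - 3, y = inv$I2 - 3,
       A1 = f$A1, B1 = f$B1, A2 = f$A2, B2 = f$B2,
       obs1 = states$P11, obs2 = states$P22, n = nrow(states))
}

#' Train the discovery network by Adam gradient descent
#'
#' Minimizes the mean squared stress error over all loading modes
#' simultaneously,
#' `L = 1/n sum_i ||P(F_i, w) - Phat_i||^2 + alpha * ||w||_1`,
#' over non-negative weights: weights are clipped at zero after every Adam
#' update. Gradients are analytic. Training stops early once the loss is
#' numerically stationary.
#'
#' @param data a `biax_data` data frame (one product) or paired-states
#'   table.
#' @param control a [cann_control()].
#' @param alpha L1 penalty; defaults to `control$l1_alpha`.
#' @param active integer subset of terms allowed to be nonzero (both
#'   weights of the other terms are frozen at zero).
#' @return List with `w`, `ws`, `loss` (final), `trajectory` (loss every
#'   100 epochs), `epochs_run`, `alpha`.
#' @export
train_cann <- function(data, control = cann_control(),
                       alpha = control$l1_alpha, active = 1:8) {
  states <- if (is.data.frame(data) && all(c("l1", "l2") %in% names(data)))
    data else paired_states(data)
  pb <- cann_problem(states)
  mask <- rep(0, 16)
  mask[active] <- 1
  mask[active + 8] <- 1

  set.seed(control$seed)
  th <- stats::runif(16) * mask
  mAd <- vAd <- rep(0, 16)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- control$learning_rate
  traj <- numeric(0)
  loss <- NA_real_

  for (ep in seq_len(control$epochs)) {
    w <- th[1:8]; ws <- th[9:16]
    E2 <- exp(ws[2] * pb$x);  E4 <- exp(ws[4] * pb$x^2)
    E6 <- exp(ws[6] * pb$y);  E8 <- exp(ws[8] * pb$y^2)
    d1 <- w[1] * ws[1] + w[2] * ws[2] * E2 + 2 * w[3] * ws[3] * pb$x +
      2 * w[4] * ws[4] * pb$x * E4
    d2 <- w[5] * ws[5] + w[6] * ws[6] * E6 + 2 * w[7] * ws[7] * pb$y +
      2 * w[8] * ws[8] * pb$y * E8
    P1 <- pb$A1 * d1 + pb$B1 * d2
    P2 <- pb$A2 * d1 + pb$B2 * d2
    r1 <- P1 - pb$obs1; r2 <- P2 - pb$obs2
    loss <- mean(r1^2 + r2^2) +
      alpha * (sum(w) + if (control$penalize_internal) sum(ws) else 0)
    if (!is.finite(loss))
      stop("training diverged (loss is not finite); reduce learning_rate",
           call. = FALSE)

    G1 <- matrix(0, pb$n, 16); G2 <- matrix(0, pb$n, 16)
    G1[, 1] <- ws[1];               G1[, 9]  <- w[1]
    G1[, 2] <- ws[2] * E2;          G1[, 10] <- w[2] * E2 * (1 + ws[2] * pb$x)
    G1[, 3] <- 2 * ws[3] * pb$x;    G1[, 11] <- 2 * w[3] * pb$x
    G1[, 4] <- 2 * ws[4] * pb$x * E4
    G1[, 12] <- 2 * w[4] * pb$x * E4 * (1 + ws[4] * pb$x^2)
    G2[, 5] <- ws[5];               G2[, 13] <- w[5]
    G2[, 6] <- ws[6] * E6;          G2[, 14] <- w[6] * E6 * (1 + ws[6] * pb$y)
    G2[, 7] <- 2 * ws[7] * pb$y;    G2[, 15] <- 2 * w[7] * pb$y
    G2[, 8] <- 2 * ws[8] * pb$y * E8
    G2[, 16] <- 2 * w[8] * pb$y * E8 * (1 + ws[8] * pb$y^2)
    D1 <- pb$A1 * G1 + pb$B1 * G2
    D2 <- pb$A2 * G1 + pb$B2 * G2
    g <- (2 / pb$n) * (crossprod(D1, r1) + crossprod(D2, r2))[, 1]
    g[1:8] <- g[1:8] + alpha
    if (control$penalize_internal) g[9:16] <- g[9:16] + alpha
    g <- g * mask

    mAd <- b1 * mAd + (1 - b1) * g
    vAd <- b2 * vAd + (1 - b2) * g^2
    th <- pmax(0, th - lr * (mAd / (1 - b1^ep)) /
                 (sqrt(vAd / (1 - b2^ep)) + eps))

    if (ep %% 100 == 0) {
      traj <- c(traj, loss)
      k <- length(traj)
      if (k > 5 &&
          abs(traj[k] - traj[k - 5]) < control$tol * max(1, abs(traj[k])))
        break
    }
  }
  list(w = th[1:8], ws = th[9:16], loss = loss, trajectory = traj,
       epochs_run = ep, alpha = alpha)
}

# Active terms: weight product above zero_threshold relative to the largest.
active_terms <- function(w, ws, zero_threshold) {
  m <- w * ws
  if (max(m) <= 0) return(integer(0))
  which(m > zero_threshold * max(m))
}

#' Discover a sparse two-term constitutive model
#'
#' Sweeps the L1 penalty upward, trains the eight-term network at each
#' value, and selects the smallest penalty whose trained weights leave
#' exactly two terms active. The selected term pair is then refit without
#' penalty (by default), and the goodness of fit is reported with the same
#' convention as the classical fits.
#'
#' @param data a `biax_data` data frame (one product).
#' @param control a [cann_control()]; `alpha_sweep` drives the selection.
#' @param product optional product id to subset `data` to.
#' @param r2_include_hold,r2_method,r2_by see [goodness_of_fit()].
#' @return Object of class `c("cann_discovery", "hyperfit")` with the
#'   refit weights, active-term indices and labels, chosen `alpha`, the
#'   penalized-fit weights, loss trajectories, and the R-squared summary.
#' @examples
#' \donttest{
#' pt <- deli_meat_means("PT")
#' disc <- discover_model(pt, cann_control(seed = 1))
#' disc$term_labels
#' }
#' @export
discover_model <- function(data, control = cann_control(), product = NULL,
                           r2_include_hold = FALSE,
                           r2_method = c("rss", "pearson"),
                           r2_by = c("curve", "mode")) {
  r2_method <- match.arg(r2_method)
  r2_by <- match.arg(r2_by)
  data <- as_biax_data(data)
  if (!is.null(product)) data <- data[data$product %in% product, ]
  states <- paired_states(data)
  if (!length(control$alpha_sweep))
    stop("alpha_sweep must be non-empty", call. = FALSE)

  profile <- data.frame(alpha = control$alpha_sweep, n_active = NA_integer_)
  chosen <- NULL
  for (i in seq_along(control$alpha_sweep)) {
    a <- control$alpha_sweep[i]
    fit <- train_cann(states, control, alpha = a)
    act <- active_terms(fit$w, fit$ws, control$zero_threshold)
    profile$n_active[i] <- length(act)
    if (length(act) == 2) { chosen <- list(fit = fit, active = act); break }
  }
  if (is.null(chosen))
    stop("no penalty in the sweep leaves exactly two active terms; ",
         "active-term profile: ",
         paste(sprintf("alpha=%.3g:%d", profile$alpha,
                       profile$n_active), collapse = ", "),
         call. = FALSE)

  penalized <- chosen$fit
  act <- chosen$active
  final <- if (control$refit)
    train_cann(states, control, alpha = 0, active = act) else penalized
  w <- final$w; ws <- final$ws
  w[-act] <- 0; ws[-act] <- 0
  energy <- energy_cann(w, ws)
  r2 <- goodness_of_fit(energy, states, include_hold = r2_include_hold,
                        method = r2_method, by = r2_by)
  structure(list(model = "cann", coefficients = c(w = w, ws = ws),
                 w = w, ws = ws, active = act,
                 term_labels = .CANN_TERMS[act],
                 alpha = penalized$alpha,
                 penalized_weights = list(w = penalized$w,
                                          ws = penalized$ws),
                 profile = profile[!is.na(profile$n_active), ],
                 trajectory = final$trajectory, energy = energy, r2 = r2,
                 loss = final$loss, states = states,
                 n = 2 * nrow(states),
                 product = product %||%
                   (if (!is.null(data$product)) unique(data$product)
                    else NULL),
                 call = match.call()),
            class = c("cann_discovery", "hyperfit"))
}

#' @export
print.cann_discovery <- function(x, ...) {
  cat("Discovered two-term constitutive model\n")
  if (!is.null(x$product)) cat("  product:", x$product, "\n")
  cat("  active terms:", paste(sprintf("%d (%s)", x$active, x$term_labels),
                               collapse = ", "), "\n")
  for (k in x$active)
    cat(sprintf("    w%d = %.4g kPa, w%d* = %.4g\n", k, x$w[k], k, x$ws[k]))
  cat(sprintf("  selected at alpha = %.3g; R2 = %.2f +/- %.2f (%s, per %s)\n",
              x$alpha, x$r2$mean, x$r2$sd, x$r2$method, x$r2$by))
  invisible(x)
}

#' Number of distinct k-term models in the discovery library
#'
#' @param k number of active terms.
#' @return `choose(8, k)`; 28 distinct two-term models for `k = 2`.
#' @export
n_term_models <- function(k = 2) choose(length(.CANN_TERMS), k)
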