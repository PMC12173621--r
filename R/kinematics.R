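# Incompressible isotropic biaxial kinematics: invariants, strain-energy
# model interface, and the analytic Piola stress for shear-free biaxial
# stretch with the plane-stress pressure eliminated.

.STRETCH_MIN <- 0.5
.STRETCH_MAX <- 2

check_stretch <- function(lambda, what = "stretch") {
  if (!is.numeric(lambda) || any(!is.finite(lambda)))
    stop(what, " must be finite numeric", call. = FALSE)
  if (any(lambda <= 0))
    stop(what, " must be positive", call. = FALSE)
  if (any(lambda < .STRETCH_MIN | lambda > .STRETCH_MAX))
    stop(what, " outside the supported range [", .STRETCH_MIN, ", ",
         .STRETCH_MAX, "]", call. = FALSE)
  invisible(lambda)
}

#' Deformation invariants of an incompressible biaxial stretch state
#'
#' For a shear-free biaxial deformation with in-plane stretches `lambda1`,
#' `lambda2` and incompressibility (`J = 1`), the thickness stretch is
#' `lambda3 = 1/(lambda1*lambda2)` and the first two invariants of the right
#' Cauchy-Green tensor reduce to
#' `I1 = lambda1^2 + lambda2^2 + (lambda1*lambda2)^-2` and
#' `I2 = lambda1^-2 + lambda2^-2 + (lambda1*lambda2)^2`.
#'
#' @param lambda1,lambda2 in-plane stretches (dimensionless, vectorized).
#' @return A list with components `I1`, `I2` (numeric vectors) and `I3`
#'   (always 1). Both invariants equal 3 if and only if the state is the
#'   reference configuration.
#' @examples
#' invariants(1, 1)        # I1 = I2 = 3
#' invariants(1.1, 1.0)    # strip stretch: I1 equals I2
#' @export
invariants <- function(lambda1, lambda2) {
  check_stretch(lambda1, "lambda1")
  check_stretch(lambda2, "lambda2")
  list(I1 = lambda1^2 + lambda2^2 + (lambda1 * lambda2)^-2,
       I2 = lambda1^-2 + lambda2^-2 + (lambda1 * lambda2)^2,
       I3 = 1)
}

#' Strain-energy model interface
#'
#' An `energy_model` bundles a strain energy density `psi(I1, I2)` (kPa) with
#' its two partial derivatives. All fitting, prediction and discovery code in
#' the package consumes this interface, so user-defined energies plug into
#' [piola_biaxial()], [goodness_of_fit()] and the plotting methods unchanged.
#'
#' The energy must vanish in the reference configuration, `psi(3, 3) = 0`;
#' the constructor checks this numerically.
#'
#' @param psi function of `(I1, I2)` returning the energy density in kPa.
#' @param dI1,dI2 functions of `(I1, I2)` returning the partial derivatives
#'   of `psi` (kPa), vectorized over their arguments.
#' @param name short label used by print methods.
#' @param parameters named list of parameter values, kept for reporting.
#' @return An object of class `energy_model`.
#' @seealso [energy_neo_hooke()], [energy_mooney_rivlin()], [energy_cann()]
#' @export
energy_model <- function(psi, dI1, dI2, name = "custom", parameters = list()) {
  stopifnot(is.function(psi), is.function(dI1), is.function(dI2))
  psi0 <- psi(3, 3)
  if (!is.finite(psi0) || abs(psi0) > 1e-8)
    stop("psi(3, 3) must be zero (stress- and energy-free reference state)",
         call. = FALSE)
  structure(list(psi = psi, dI1 = dI1, dI2 = dI2, name = name,
                 parameters = parameters),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Strain-energy model:", x$name, "\n")
  if (length(x$parameters)) {
    p <- unlist(x$parameters)
    cat("  parameters:",
        paste(names(p), signif(p, 4), sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Neo-Hookean strain energy
#'
#' `psi = c1/2 * (I1 - 3)` with a single stiffness-like parameter `c1` (kPa).
#' Under this 1/2-convention the shear modulus is `mu = c1`.
#'
#' @param c1 parameter in kPa.
#' @return An [energy_model()].
#' @export
energy_neo_hooke <- function(c1) {
  stopifnot(is.numeric(c1), length(c1) == 1, is.finite(c1))
  force(c1)
  energy_model(
    psi = function(I1, I2) 0.5 * c1 * (I1 - 3),
    dI1 = function(I1, I2) rep_len(0.5 * c1, length(I1)),
    dI2 = function(I1, I2) rep_len(0, length(I1)),
    name = "neo-Hooke", parameters = list(c1 = c1))
}

#' Mooney-Rivlin strain energy
#'
#' `psi = c1/2 * (I1 - 3) + c2/2 * (I2 - 3)`; the neo-Hookean model is the
#' special case `c2 = 0`. Shear modulus `mu = c1 + c2`.
#'
#' @param c1,c2 parameters in kPa.
#' @return An [energy_model()].
#' @export
energy_mooney_rivlin <- function(c1, c2) {
  stopifnot(is.numeric(c1), length(c1) == 1, is.finite(c1),
            is.numeric(c2), length(c2) == 1, is.finite(c2))
  force(c1); force(c2)
  energy_model(
    psi = function(I1, I2) 0.5 * c1 * (I1 - 3) + 0.5 * c2 * (I2 - 3),
    dI1 = function(I1, I2) rep_len(0.5 * c1, length(I1)),
    dI2 = function(I1, I2) rep_len(0.5 * c2, length(I1)),
    name = "Mooney-Rivlin", parameters = list(c1 = c1, c2 = c2))
}

# Geometric stress factors of the plane-stress biaxial relation:
# P11 = A1 * dpsi/dI1 + B1 * dpsi/dI2, P22 = A2 * dpsi/dI1 + B2 * dpsi/dI2.
# Eliminating the incompressibility pressure through P33 = 0 gives
# A1 = 2(l1 - 1/(l1^3 l2^2)), B1 = 2(l1 l2^2 - 1/l1^3) and the symmetric
# counterparts with indices swapped.
biax_factors <- function(lambda1, lambda2) {
  list(A1 = 2 * (lambda1 - 1 / (lambda1^3 * lambda2^2)),
       B1 = 2 * (lambda1 * lambda2^2 - 1 / lambda1^3),
       A2 = 2 * (lambda2 - 1 / (lambda1^2 * lambda2^3)),
       B2 = 2 * (lambda1^2 * lambda2 - 1 / lambda2^3))
}

#' Biaxial Piola stresses for a strain-energy model
#'
#' Evaluates the in-plane Piola (nominal) stresses of an incompressible,
#' isotropic hyperelastic material in shear-free biaxial extension. The
#' incompressibility pressure is eliminated analytically through the
#' zero-thickness-stress condition `P33 = 0`, giving
#' \deqn{P_{11} = 2[\lambda_1 - \lambda_1^{-3}\lambda_2^{-2}]
#'   \partial\psi/\partial I_1 +
#'   2[\lambda_1\lambda_2^2 - \lambda_1^{-3}] \partial\psi/\partial I_2}
#' and the symmetric expression for `P22`.
#'
#' @param model an [energy_model()].
#' @param lambda1,lambda2 in-plane stretches (vectorized).
#' @return A list with numeric vectors `P11` and `P22` in kPa.
#' @examples
#' nh <- energy_neo_hooke(126.1)
#' piola_biaxial(nh, 1.1, 1.1)   # equibiaxial: P11 = P22
#' @export
piola_biaxial <- function(model, lambda1, lambda2) {
  stopifnot(inherits(model, "energy_model"))
  n <- max(length(lambda1), length(lambda2))
  lambda1 <- rep_len(lambda1, n)
  lambda2 <- rep_len(lambda2, n)
  inv <- invariants(lambda1, lambda2)
  d1 <- model$dI1(inv$I1, inv$I2)
  d2 <- model$dI2(inv$I1, inv$I2)
  if (any(!is.finite(d1)) || any(!is.finite(d2))) {
    bad <- which(!is.finite(d1) | !is.finite(d2))[1]
    stop(sprintf(paste0("non-finite energy derivative at I1 = %.6g, ",
                        "I2 = %.6g"), inv$I1[bad], inv$I2[bad]), call. = FALSE)
  }
  f <- biax_factors(lambda1, lambda2)
  list(P11 = f$A1 * d1 + f$B1 * d2,
       P22 = f$A2 * d1 + f$B2 * d2)
}
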