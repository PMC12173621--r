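# Closed-form neo-Hookean / Mooney-Rivlin stresses, linear least-squares
# parameter identification, elastic moduli, and goodness of fit.

#' Closed-form classical model stresses
#'
#' Direct evaluation of the biaxial Piola stresses of the two classical
#' models, `P11 = c1[l1 - 1/(l1^3 l2^2)] + c2[l1 l2^2 - 1/l1^3]` and its
#' symmetric counterpart; `nh_stress()` is the `c2 = 0` special case. These
#' agree with [piola_biaxial()] applied to [energy_neo_hooke()] /
#' [energy_mooney_rivlin()] to machine precision.
#'
#' @param c1,c2 model parameters in kPa.
#' @param lambda1,lambda2 in-plane stretches (vectorized).
#' @return List with vectors `P11`, `P22` in kPa.
#' @export
mr_stress <- function(c1, c2, lambda1, lambda2) {
  check_stretch(lambda1, "lambda1")
  check_stretch(lambda2, "lambda2")
  list(P11 = c1 * (lambda1 - 1 / (lambda1^3 * lambda2^2)) +
         c2 * (lambda1 * lambda2^2 - 1 / lambda1^3),
       P22 = c1 * (lambda2 - 1 / (lambda1^2 * lambda2^3)) +
         c2 * (lambda1^2 * lambda2 - 1 / lambda2^3))
}

#' @rdname mr_stress
#' @export
nh_stress <- function(c1, lambda1, lambda2) {
  mr_stress(c1, 0, lambda1, lambda2)
}

#' Elastic moduli of an incompressible classical fit
#'
#' Shear modulus `mu = c1` (neo-Hooke) or `mu = c1 + c2` (Mooney-Rivlin);
#' for an incompressible material (`nu = 0.5`) the elastic modulus is
#' `E = 2 mu (1 + nu) = 3 mu`.
#'
#' @param params numeric vector: `c1` or `c(c1, c2)`.
#' @param model `"neo-hooke"` or `"mooney-rivlin"`; inferred from the length
#'   of `params` when missing.
#' @return List with `mu`, `E` (kPa) and `nu = 0.5`.
#' @examples
#' elastic_moduli(44.66)            # E = 134.0 kPa
#' elastic_moduli(c(160, -30.95))   # E = 387.2 kPa
#' @export
elastic_moduli <- function(params, model = NULL) {
  if (is.null(model))
    model <- if (length(params) >= 2) "mooney-rivlin" else "neo-hooke"
  model <- match.arg(model, c("neo-hooke", "mooney-rivlin"))
  mu <- if (model == "neo-hooke") params[[1]] else params[[1]] + params[[2]]
  list(mu = unname(mu), E = unname(3 * mu), nu = 0.5)
}

# Reshape a long biax_data block (one product) into paired deformation
# states: one row per grid point per mode with (l1, l2, P11, P22). The x and
# y rows of a mode are paired by position; equal counts are required.
paired_states <- function(data) {
  data <- as_biax_data(data)
  if (!is.null(data$product) && length(unique(data$product)) > 1)
    stop("data contains multiple products; subset or pass product = ",
         call. = FALSE)
  out <- lapply(intersect(.MODES, unique(data$mode)), function(m) {
    x <- data[data$mode == m & data$direction == "x", ]
    y <- data[data$mode == m & data$direction == "y", ]
    if (!nrow(x) || !nrow(y))
      stop("mode ", m, " is missing a direction", call. = FALSE)
    if (nrow(x) != nrow(y))
      stop("mode ", m, ": x and y channels have different lengths",
           call. = FALSE)
    data.frame(mode = m, l1 = x$stretch, l2 = y$stretch,
               P11 = x$stress_kPa, P22 = y$stress_kPa)
  })
  do.call(rbind, out)
}

# Linear design of the classical models: rows stack the P11 then the P22
# component of every state; columns are the c1 and c2 basis responses.
classical_design <- function(states, include_hold = TRUE) {
  s <- states
  if (!include_hold) {
    # drop the held component of strip modes (P22 of strip-x, P11 of strip-y)
    keep11 <- s$mode != "strip-y"
    keep22 <- s$mode != "strip-x"
  } else {
    keep11 <- keep22 <- rep(TRUE, nrow(s))
  }
  f <- biax_factors(s$l1, s$l2)
  b1 <- mr_stress(1, 0, s$l1, s$l2)
  b2 <- mr_stress(0, 1, s$l1, s$l2)
  A <- cbind(c1 = c(b1$P11[keep11], b1$P22[keep22]),
             c2 = c(b2$P11[keep11], b2$P22[keep22]))
  y <- c(s$P11[keep11], s$P22[keep22])
  list(A = A, y = y)
}

#' Fit a classical hyperelastic model to biaxial data
#'
#' The central fitting function of the package. Both classical models are
#' linear in their parameters, so the fit is an unweighted ordinary linear
#' least-squares problem stacking both stress components of every retained
#' deformation state across all loading modes:
#' \deqn{L = \sum_i \|P_{11}(\lambda_{1i},\lambda_{2i}) - \hat P_{11,i}\|^2
#'         + \|P_{22}(\lambda_{1i},\lambda_{2i}) - \hat P_{22,i}\|^2.}
#' Held channels of the strip modes are included in the fit by default
#' (`include_hold = TRUE`) but excluded from the reported goodness of fit
#' (`r2_include_hold = FALSE`); both are independently togglable.
#'
#' @param data a `biax_data` data frame (see [as_biax_data()]), e.g. one
#'   product of [deli_meat_means()].
#' @param model `"neo-hooke"` (one parameter) or `"mooney-rivlin"` (two).
#' @param product optional product id to subset `data` to.
#' @param include_hold include held strip-mode channels in the least-squares
#'   stack.
#' @param r2_include_hold include held channels in the R-squared summary.
#' @param r2_method,r2_by goodness-of-fit convention, see
#'   [goodness_of_fit()].
#' @return An object of class `hyperfit` with components `coefficients`,
#'   `moduli` (list `mu`, `E`, `nu`), `energy` (an [energy_model()]), `r2`
#'   (per-curve table plus mean/sd), `loss` (residual sum of squares of the
#'   stacked problem), `states`, `n`.
#' @examples
#' fit <- fit_hyperelastic(deli_meat_means("PT"), "neo-hooke")
#' coef(fit)
#' fit$moduli$E
#' @export
fit_hyperelastic <- function(data, model = c("neo-hooke", "mooney-rivlin"),
                             product = NULL, include_hold = TRUE,
                             r2_include_hold = FALSE,
                             r2_method = c("rss", "pearson"),
                             r2_by = c("curve", "mode")) {
  model <- match.arg(model)
  r2_method <- match.arg(r2_method)
  r2_by <- match.arg(r2_by)
  data <- as_biax_data(data)
  if (!is.null(product)) data <- data[data$product %in% product, ]
  states <- paired_states(data)
  des <- classical_design(states, include_hold = include_hold)
  A <- if (model == "neo-hooke") des$A[, 1, drop = FALSE] else des$A
  keep <- rowSums(abs(A)) > 0 | des$y != 0   # drop all-zero reference rows
  if (sum(keep) < ncol(A))
    stop("too few distinct stretch states with nonzero stress",
         call. = FALSE)
  ls <- stats::lm.fit(A[keep, , drop = FALSE], des$y[keep])
  if (ls$rank < ncol(A))
    stop("singular fit: design is rank deficient (all states at lambda = 1?)",
         call. = FALSE)
  cf <- ls$coefficients
  energy <- if (model == "neo-hooke") energy_neo_hooke(cf[["c1"]])
            else energy_mooney_rivlin(cf[["c1"]], cf[["c2"]])
  r2 <- goodness_of_fit(energy, states, include_hold = r2_include_hold,
                        method = r2_method, by = r2_by)
  structure(list(model = model, coefficients = cf,
                 moduli = elastic_moduli(cf, model), energy = energy,
                 r2 = r2, loss = sum(ls$residuals^2), states = states,
                 n = sum(keep), product = product %||%
                   (if (!is.null(data$product)) unique(data$product) else NULL),
                 call = match.call()),
            class = "hyperfit")
}

#' Goodness of fit of an energy model to biaxial data
#'
#' The default convention reproduces the package's reference analyses:
#' R-squared is computed per stress-stretch curve (x and y channels of
#' off-x, off-y and equibiax; only the stretched channel of the strip modes)
#' as `1 - SS_res/SS_tot`, truncated at zero, and summarized as mean and
#' standard deviation across the retained curves. Alternatives:
#' `method = "pearson"` uses the squared Pearson correlation between
#' predictions and measurements (scale- and offset-insensitive), and
#' `by = "mode"` pools the two directions of each mode into a single value
#' (five values instead of eight).
#'
#' Curves with constant measured stress have no defined R-squared; they are
#' reported as `NA` and excluded from the mean with a warning.
#'
#' @param model an [energy_model()].
#' @param data a `biax_data` data frame or a paired-states data frame.
#' @param include_hold include held strip-mode channels.
#' @param method `"rss"` (1 - SSres/SStot, clipped to `[0, 1]`) or
#'   `"pearson"` (squared correlation).
#' @param by `"curve"` or `"mode"`.
#' @param clip truncate negative `"rss"` values at zero.
#' @return List with `table` (per-curve/mode data frame), `mean`, `sd`,
#'   `method`, `by`.
#' @export
goodness_of_fit <- function(model, data, include_hold = FALSE,
                            method = c("rss", "pearson"),
                            by = c("curve", "mode"), clip = TRUE) {
  method <- match.arg(method)
  by <- match.arg(by)
  states <- if (is.data.frame(data) && all(c("l1", "l2") %in% names(data)))
    data else paired_states(data)
  pred <- piola_biaxial(model, states$l1, states$l2)

  one_r2 <- function(obs, hat) {
    if (length(obs) < 2 || stats::sd(obs) == 0) return(NA_real_)
    if (method == "pearson") return(stats::cor(obs, hat)^2)
    r2 <- 1 - sum((obs - hat)^2) / sum((obs - mean(obs))^2)
    if (clip) max(0, min(1, r2)) else r2
  }

  rows <- list()
  for (m in intersect(.MODES, unique(states$mode))) {
    s <- states$mode == m
    chans <- list(x = list(obs = states$P11[s], hat = pred$P11[s]),
                  y = list(obs = states$P22[s], hat = pred$P22[s]))
    hd <- hold_direction(m)
    if (!include_hold && !is.na(hd)) chans[[hd]] <- NULL
    if (by == "mode") {
      obs <- unlist(lapply(chans, `[[`, "obs"))
      hat <- unlist(lapply(chans, `[[`, "hat"))
      rows[[length(rows) + 1]] <-
        data.frame(mode = m, direction = "both", r2 = one_r2(obs, hat))
    } else {
      for (d in names(chans))
        rows[[length(rows) + 1]] <-
          data.frame(mode = m, direction = d,
                     r2 = one_r2(chans[[d]]$obs, chans[[d]]$hat))
    }
  }
  tab <- do.call(rbind, rows)
  if (anyNA(tab$r2))
    warning("constant measured stress in ",
            sum(is.na(tab$r2)), " curve(s); excluded from the R2 summary",
            call. = FALSE)
  list(table = tab, mean = mean(tab$r2, na.rm = TRUE),
       sd = stats::sd(tab$r2, na.rm = TRUE), method = method, by = by)
}

#' Per-sample fits and their summary
#'
#' Fits the requested model to each sample's dataset individually and
#' reports the parameter table together with across-sample mean and
#' standard deviation. This is the convention used for reporting parameters
#' and moduli of replicated experiments, complementary to a single fit to
#' the averaged data.
#'
#' @param datasets list of `biax_data` data frames, one per sample.
#' @param model passed to [fit_hyperelastic()].
#' @param ... further arguments to [fit_hyperelastic()].
#' @return List with `fits` (list of `hyperfit`), `params` (per-sample
#'   coefficient table with `mu` and `E`), `mean`, `sd`.
#' @export
fit_samples <- function(datasets, model = c("neo-hooke", "mooney-rivlin"),
                        ...) {
  model <- match.arg(model)
  fits <- lapply(datasets, fit_hyperelastic, model = model, ...)
  params <- do.call(rbind, lapply(fits, function(f)
    c(f$coefficients, mu = f$moduli$mu, E = f$moduli$E)))
  params <- as.data.frame(params)
  list(fits = fits, params = params,
       mean = colMeans(params), sd = apply(params, 2, stats::sd))
}

# ---- hyperfit methods -------------------------------------------------

#' @export
print.hyperfit <- function(x, ...) {
  cat("Incompressible hyperelastic fit:", x$model, "\n")
  if (!is.null(x$product)) cat("  product:", x$product, "\n")
  cat("  coefficients (kPa):",
      paste(names(x$coefficients), signif(x$coefficients, 4),
            sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  shear modulus mu = %.4g kPa, stiffness E = 3 mu = %.4g kPa\n",
              x$moduli$mu, x$moduli$E))
  cat(sprintf("  R2 = %.2f +/- %.2f (%s, per %s)\n",
              x$r2$mean, x$r2$sd, x$r2$method, x$r2$by))
  invisible(x)
}

#' @export
summary.hyperfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.hyperfit")
}

#' @export
print.summary.hyperfit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  stacked least-squares points:", f$n,
      " residual sum of squares:", signif(f$loss, 5), "kPa^2\n")
  cat("  goodness of fit by curve:\n")
  tab <- f$r2$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("    %-9s %-4s R2 = %s\n", tab$mode[i], tab$direction[i],
                ifelse(is.na(tab$r2[i]), "NA", sprintf("%.3f", tab$r2[i]))))
  invisible(x)
}

#' @export
coef.hyperfit <- function(object, ...) object$coefficients

#' Predict biaxial stresses from a fitted model
#'
#' @param object a `hyperfit` (or discovery) object.
#' @param newdata data frame with columns `lambda1` and `lambda2`; defaults
#'   to the fitted states.
#' @param ... unused.
#' @return Data frame with `lambda1`, `lambda2`, `P11`, `P22`.
#' @export
predict.hyperfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- data.frame(lambda1 = object$states$l1,
                          lambda2 = object$states$l2)
  p <- piola_biaxial(object$energy, newdata$lambda1, newdata$lambda2)
  data.frame(lambda1 = newdata$lambda1, lambda2 = newdata$lambda2,
             P11 = p$P11, P22 = p$P22)
}

#' @export
fitted.hyperfit <- function(object, ...) {
  p <- piola_biaxial(object$energy, object$states$l1, object$states$l2)
  cbind(object$states[c("mode", "l1", "l2")], P11 = p$P11, P22 = p$P22)
}

#' @export
residuals.hyperfit <- function(object, ...) {
  p <- piola_biaxial(object$energy, object$states$l1, object$states$l2)
  cbind(object$states[c("mode", "l1", "l2")],
        P11 = object$states$P11 - p$P11,
        P22 = object$states$P22 - p$P22)
}

#' Plot data and model predictions per loading mode
#'
#' One panel per loading mode: measured stresses (points) and model
#' predictions (lines) against the leading-direction stretch, for both
#' stress components.
#'
#' @param x a `hyperfit` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hyperfit <- function(x, ...) {
  s <- x$states
  modes <- intersect(.MODES, unique(s$mode))
  old <- graphics::par(mfrow = c(1, length(modes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  pred <- piola_biaxial(x$energy, s$l1, s$l2)
  for (m in modes) {
    i <- s$mode == m
    lead <- if (leading_direction(m) == "x") s$l1[i] else s$l2[i]
    ylim <- range(0, s$P11[i], s$P22[i], pred$P11[i], pred$P22[i])
    graphics::plot(lead, s$P11[i], pch = 16, ylim = ylim, main = m,
                   xlab = expression(lambda), ylab = "P [kPa]", ...)
    graphics::points(lead, s$P22[i], pch = 1)
    graphics::lines(lead, pred$P11[i], lty = 1)
    graphics::lines(lead, pred$P22[i], lty = 2)
  }
  invisible(x)
}

#' Simulate replicated experiments from a fitted model
#'
#' Uses the fitted energy as ground truth for the synthetic biaxial
#' generator, producing `nsim` per-sample datasets that mimic the protocol
#' of the fitted data (noise and hysteresis configurable through `spec`).
#'
#' @param object a `hyperfit` object.
#' @param nsim number of samples to simulate.
#' @param seed RNG seed.
#' @param ... overrides for [ground_truth_spec()] fields.
#' @return List of `biax_data` datasets, one per simulated sample.
#' @export
simulate.hyperfit <- function(object, nsim = 1, seed = NULL, ...) {
  spec <- ground_truth_spec(model = object$energy, n_samples = nsim,
                            seed = seed %||% 1, ...)
  simulate_biaxial_samples(spec, as_datasets = TRUE)
}
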