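# Seeded generators for biaxial recordings and sensory panels with known
# ground truth, so that every pipeline stage is testable end to end.

#' Ground-truth specification for the biaxial generator
#'
#' Describes a virtual material and test: the true strain-energy model, the
#' sample geometry, the noise and hysteresis levels, and the stretch
#' protocol. Defaults mirror the laboratory protocol the package targets:
#' 12 x 12 mm gauge region, 30 mN preload, 1 %/s stretch rate to
#' `lambda = 1.1`, three stretch-recovery cycles, n = 8 samples, 5 %
#' multiplicative noise.
#'
#' Hysteresis is modeled as a symmetric multiplicative split about the
#' elastic curve, `P = P_elastic * (1 +/- gap * sin(pi * s))` with `s` the
#' loading progress, so the loop closes at both turning points and the
#' loading/unloading average recovers the elastic curve exactly.
#'
#' @param model an [energy_model()] (the true material).
#' @param thickness sample thickness in mm.
#' @param noise_sigma relative noise level; multiplicative lognormal by
#'   default.
#' @param hysteresis_gap relative loading/unloading split (0 = elastic).
#' @param n_samples number of replicate samples.
#' @param protocol a [test_protocol()].
#' @param gauge reference gauge lengths `c(L1, L2)` in mm.
#' @param noise_type `"multiplicative"` (lognormal) or `"additive"`
#'   (Gaussian with sd `noise_sigma * max |P|` per curve).
#' @param seed RNG seed; equal specs reproduce bit for bit.
#' @return List of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(model, thickness = 0.9, noise_sigma = 0.05,
                              hysteresis_gap = 0.1, n_samples = 8,
                              protocol = test_protocol(),
                              gauge = c(12, 12),
                              noise_type = c("multiplicative", "additive"),
                              seed = 1) {
  stopifnot(inherits(model, "energy_model"), thickness > 0,
            noise_sigma >= 0, hysteresis_gap >= 0, n_samples >= 1,
            inherits(protocol, "test_protocol"), all(gauge > 0))
  structure(list(model = model, thickness = thickness,
                 noise_sigma = noise_sigma,
                 hysteresis_gap = hysteresis_gap,
                 n_samples = as.integer(n_samples), protocol = protocol,
                 gauge = gauge, noise_type = match.arg(noise_type),
                 seed = seed),
            class = "ground_truth_spec")
}

# (lambda1, lambda2) coupling of each mode given the leading ramp:
# strips hold one axis, equibiax moves both equally, off modes drive the
# trailing axis as the square root of the leading stretch.
mode_stretch_path <- function(mode, lead) {
  switch(mode,
         "strip-x" = list(l1 = lead, l2 = rep(1, length(lead))),
         "strip-y" = list(l1 = rep(1, length(lead)), l2 = lead),
         "equibiax" = list(l1 = lead, l2 = lead),
         "off-x" = list(l1 = lead, l2 = sqrt(lead)),
         "off-y" = list(l1 = sqrt(lead), l2 = lead),
         stop("unknown mode: ", mode, call. = FALSE))
}

# One synthetic recording: preload ramp reaching exactly the preload force
# at the reference gauge lengths, then `cycles` triangular stretch cycles.
simulate_recording <- function(spec, mode, sample_id, dt = 0.5) {
  pr <- spec$protocol
  L1 <- spec$gauge[1]; L2 <- spec$gauge[2]; t <- spec$thickness
  n_ramp <- max(5, round((pr$max_stretch - 1) / (pr$stretch_rate * dt)))
  up <- seq(1, pr$max_stretch, length.out = n_ramp + 1)
  down <- rev(up)[-1]
  lead <- 1
  phase_sign <- 0                      # +1 loading, -1 unloading
  for (k in seq_len(pr$cycles)) {
    lead <- c(lead, up[-1], down)
    phase_sign <- c(phase_sign, rep(1, n_ramp), rep(-1, n_ramp))
  }
  path <- mode_stretch_path(mode, lead)
  p <- piola_biaxial(spec$model, path$l1, path$l2)

  # loop-closing hysteresis split, then noise
  s <- (lead - 1) / (pr$max_stretch - 1)
  hfac <- 1 + spec$hysteresis_gap * sin(pi * s) * phase_sign
  P11 <- p$P11 * hfac
  P22 <- p$P22 * hfac
  if (spec$noise_sigma > 0) {
    if (spec$noise_type == "multiplicative") {
      P11 <- P11 * exp(stats::rnorm(length(P11), 0, spec$noise_sigma))
      P22 <- P22 * exp(stats::rnorm(length(P22), 0, spec$noise_sigma))
    } else {
      sd11 <- spec$noise_sigma * max(abs(P11), 1e-12)
      sd22 <- spec$noise_sigma * max(abs(P22), 1e-12)
      P11 <- P11 + stats::rnorm(length(P11), 0, sd11)
      P22 <- P22 + stats::rnorm(length(P22), 0, sd22)
    }
  }

  # preload ramp: forces rise linearly to exactly the preload as the gauges
  # approach the reference lengths; the preload is carried through the test
  # as an additive baseline and removed downstream by re-anchoring
  n_pre <- 6
  pre_f <- seq(0, 1, length.out = n_pre)
  force_x <- c(pre_f * pr$preload, (P11 * L2 * t + pr$preload)[-1])
  force_y <- c(pre_f * pr$preload, (P22 * L1 * t + pr$preload)[-1])
  gauge_x <- c(L1 * seq(0.995, 1, length.out = n_pre), (path$l1 * L1)[-1])
  gauge_y <- c(L2 * seq(0.995, 1, length.out = n_pre), (path$l2 * L2)[-1])
  time <- seq_along(force_x) * dt
  biaxial_recording(time, force_x, force_y, gauge_x, gauge_y,
                    thickness = t, mode = mode, sample_id = sample_id)
}

#' Simulate replicate biaxial experiments
#'
#' Generates `n_samples` virtual samples, each tested in all five loading
#' modes with the spec's protocol: stress paths follow each mode's stretch
#' coupling, loading/unloading are split symmetrically about the elastic
#' curve, noise is applied per point, and forces/gauge lengths are
#' back-computed so the raw-processing pipeline round-trips.
#'
#' @param spec a [ground_truth_spec()].
#' @param as_datasets if `TRUE`, run each sample through the standard
#'   pipeline (gauge reference, final-cycle extraction, resampling and
#'   loading/unloading averaging) and return `biax_data` datasets instead
#'   of raw recordings.
#' @param n_points resampling grid size when `as_datasets = TRUE`.
#' @param cycle which cycle to process (defaults to the protocol's last).
#' @return A list with one element per sample: either a named list of
#'   [biaxial_recording()] (one per mode) or a `biax_data` data frame.
#' @export
simulate_biaxial_samples <- function(spec, as_datasets = FALSE,
                                     n_points = 11, cycle = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  set.seed(spec$seed)
  samples <- lapply(seq_len(spec$n_samples), function(si) {
    recs <- lapply(spec$protocol$mode_order, function(m)
      simulate_recording(spec, m, sample_id = paste0("s", si)))
    names(recs) <- spec$protocol$mode_order
    recs
  })
  if (!as_datasets) return(samples)
  lapply(samples, process_recordings, protocol = spec$protocol,
         n_points = n_points, cycle = cycle)
}

#' Process a set of recordings into an averaged dataset
#'
#' The standard raw-data pipeline for one sample: find the preload-defined
#' gauge reference, convert to stretch/stress, extract the loading and
#' unloading halves of the requested cycle for every mode, resample both on
#' a common grid and average them.
#'
#' @param recordings named list of [biaxial_recording()], one per mode.
#' @param protocol a [test_protocol()].
#' @param n_points resampling grid size.
#' @param cycle cycle to extract; defaults to the protocol's last cycle.
#' @return A `biax_data` data frame covering all supplied modes.
#' @export
process_recordings <- function(recordings, protocol = test_protocol(),
                               n_points = 11, cycle = NULL) {
  cycle <- cycle %||% protocol$cycles
  out <- lapply(recordings, function(rec) {
    ref <- set_gauge_reference(rec, protocol)
    curves <- to_stretch_stress(rec, ref)
    resample_and_average(list(extract_cycle(curves, cycle, "loading"),
                              extract_cycle(curves, cycle, "unloading")),
                         n_points = n_points)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(res, class = c("biax_data", "data.frame"))
}

# Table of virtual products emulating the stiffness ladder of commercial
# deli meats: three stiff wheat-gluten products, an intermediate group, and
# soft prosciutto-style products (which also tolerate 25 % stretch). One
# product (AP) is an exact two-parameter Mooney-Rivlin material so that
# model discovery has a recoverable {I1 linear, I2 linear} ground truth.
fixture_products <- function() {
  list(
    PT = list(model = "neo-hooke", params = c(c1 = 126.1), max_stretch = 1.10),
    PH = list(model = "neo-hooke", params = c(c1 = 114.4), max_stretch = 1.10),
    PD = list(model = "neo-hooke", params = c(c1 = 71.1),  max_stretch = 1.10),
    PP = list(model = "neo-hooke", params = c(c1 = 37.5),  max_stretch = 1.25),
    AT = list(model = "neo-hooke", params = c(c1 = 44.7),  max_stretch = 1.10),
    AC = list(model = "neo-hooke", params = c(c1 = 39.1),  max_stretch = 1.10),
    AH = list(model = "mooney-rivlin", params = c(c1 = 17.9, c2 = 19.1),
              max_stretch = 1.10),
    AP = list(model = "mooney-rivlin", params = c(c1 = 7.43, c2 = 7.20),
              max_stretch = 1.25))
}

#' Synthetic eight-product panel with known ground truth
#'
#' Builds a full eight-product collection of averaged biaxial datasets
#' whose true moduli ladder mirrors the span of commercial deli products
#' (stiff plant-based sheets down to soft animal prosciutto). Two products
#' are true Mooney-Rivlin materials, one of them exactly the two-term
#' `{I1 linear, I2 linear}` model, giving model discovery a recoverable
#' target.
#'
#' @param seed RNG seed; the ground-truth parameters never change with the
#'   seed, only the noise does.
#' @param n_samples replicate samples per product.
#' @param noise_sigma,hysteresis_gap passed to [ground_truth_spec()].
#' @param n_points resampling grid size.
#' @return List with `data` (combined across-sample mean `biax_data` with a
#'   `product` column), `samples` (per-product list of per-sample
#'   datasets), and `truth` (per-product list: model kind, parameters,
#'   `mu`, `E`).
#' @export
make_fixture_panel <- function(seed = 1, n_samples = 8, noise_sigma = 0.05,
                               hysteresis_gap = 0.1, n_points = 11) {
  prods <- fixture_products()
  truth <- list()
  all_means <- list()
  all_samples <- list()
  for (pid in names(prods)) {
    pp <- prods[[pid]]
    model <- if (pp$model == "neo-hooke") energy_neo_hooke(pp$params[["c1"]])
             else energy_mooney_rivlin(pp$params[["c1"]], pp$params[["c2"]])
    spec <- ground_truth_spec(
      model, noise_sigma = noise_sigma, hysteresis_gap = hysteresis_gap,
      n_samples = n_samples,
      protocol = test_protocol(max_stretch = pp$max_stretch),
      seed = seed + match(pid, names(prods)))
    recs <- simulate_biaxial_samples(spec)
    sample_sets <- lapply(recs, process_recordings, protocol = spec$protocol,
                          n_points = n_points)
    # across-sample mean per mode, averaging each sample's final-cycle
    # loading and unloading curves together
    mode_means <- lapply(spec$protocol$mode_order, function(m) {
      curves <- unlist(lapply(recs, function(sample) {
        ref <- set_gauge_reference(sample[[m]], spec$protocol)
        cv <- to_stretch_stress(sample[[m]], ref)
        list(extract_cycle(cv, spec$protocol$cycles, "loading"),
             extract_cycle(cv, spec$protocol$cycles, "unloading"))
      }), recursive = FALSE)
      resample_and_average(curves, n_points = n_points)
    })
    means <- do.call(rbind, c(mode_means, make.row.names = FALSE))
    means <- cbind(product = pid, means)
    mod <- elastic_moduli(pp$params, pp$model)
    truth[[pid]] <- list(model = pp$model, params = pp$params,
                         mu = mod$mu, E = mod$E)
    all_means[[pid]] <- means
    all_samples[[pid]] <- sample_sets
  }
  data <- do.call(rbind, c(all_means, make.row.names = FALSE))
  list(data = structure(data, class = c("biax_data", "data.frame")),
       samples = all_samples, truth = truth)
}

#' Survey link specification
#'
#' Describes how latent sensory intensities depend on physical stiffness:
#' each feature's latent mean is `intercept + slope * z`, where `z` is the
#' standardized log stiffness of the product; participant noise is added
#' and the result discretized to the 1..5 scale by rounding (thresholds at
#' half-integers). Positive slopes make stiffer products score higher.
#'
#' @param slopes named numeric vector of per-feature slopes (Likert points
#'   per sd of log stiffness); unnamed features default to 0. The default
#'   links make stiffer products more brittle, harder and chewier, and
#'   softer products moister, fattier, meatier and more fibrous.
#' @param intercept latent grand mean on the 1..5 scale.
#' @param noise_sd participant noise, Likert points.
#' @param instrument_targets named list of target mean totals for the two
#'   questionnaires.
#' @param instrument_sd across-participant sd of questionnaire totals.
#' @return List of class `survey_link_spec`.
#' @export
survey_link_spec <- function(slopes = c(brittle = 0.9, hard = 0.5,
                                        chewy = 0.35, gummy = 0.2,
                                        springy = 0, viscous = 0,
                                        sticky = 0, soft = -0.6,
                                        moist = -0.55, fatty = -0.6,
                                        fibrous = -0.35, meaty = -0.4),
                             intercept = 3, noise_sd = 0.8,
                             instrument_targets = list(neophobia = 24.3,
                                                       meat_attachment = 48.7),
                             instrument_sd = 8) {
  stopifnot(is.numeric(slopes), !is.null(names(slopes)), noise_sd >= 0)
  bad <- setdiff(names(slopes), .FEATURES)
  if (length(bad))
    stop("unknown features in slopes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  full <- stats::setNames(rep(0, length(.FEATURES)), .FEATURES)
  full[names(slopes)] <- slopes
  structure(list(slopes = full, intercept = intercept, noise_sd = noise_sd,
                 instrument_targets = instrument_targets,
                 instrument_sd = instrument_sd),
            class = "survey_link_spec")
}

# item responses whose scored total lands near `target`; raw responses are
# stored with reverse-coded items reflected back
draw_instrument <- function(instr, participants, target, spread) {
  out <- list()
  for (pid in participants) {
    total <- round(stats::rnorm(1, target, spread))
    total <- min(max(total, instr$score_range[1]), instr$score_range[2])
    base <- total / instr$n_items
    scored <- round(base + stats::rnorm(instr$n_items, 0, 0.8))
    scored <- pmin(pmax(scored, 1), instr$scale_points)
    raw <- scored
    rev <- seq_len(instr$n_items) %in% instr$reverse_items
    raw[rev] <- instr$scale_points + 1L - scored[rev]
    out[[pid]] <- data.frame(participant = pid,
                             item = seq_len(instr$n_items), response = raw)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a sensory texture panel with a latent stiffness link
#'
#' @param link a [survey_link_spec()].
#' @param stiffness_by_product named numeric vector of physical stiffness
#'   (kPa) per product.
#' @param n_participants panel size.
#' @param seed RNG seed.
#' @return List with `table` (a [likert_table()]), `instruments` (response
#'   data frames for the neophobia and meat-attachment questionnaires),
#'   and `latent` (the noise-free latent means per product and feature).
#' @export
simulate_survey <- function(link = survey_link_spec(), stiffness_by_product,
                            n_participants = 18, seed = 1) {
  stopifnot(inherits(link, "survey_link_spec"),
            !is.null(names(stiffness_by_product)))
  set.seed(seed)
  z <- scale(log(stiffness_by_product))[, 1]
  products <- names(stiffness_by_product)
  participants <- sprintf("p%02d", seq_len(n_participants))
  latent <- outer(z, link$slopes) + link$intercept   # product x feature
  rows <- expand.grid(participant = participants, product = products,
                      feature = .FEATURES, stringsAsFactors = FALSE)
  mu <- latent[cbind(match(rows$product, products),
                     match(rows$feature, .FEATURES))]
  score <- round(mu + stats::rnorm(nrow(rows), 0, link$noise_sd))
  rows$score <- as.integer(pmin(pmax(score, 1L), 5L))
  instruments <- list(
    neophobia = draw_instrument(instrument("neophobia"), participants,
                                link$instrument_targets$neophobia,
                                link$instrument_sd),
    meat_attachment = draw_instrument(instrument("meat_attachment"),
                                      participants,
                                      link$instrument_targets$meat_attachment,
                                      link$instrument_sd))
  list(table = likert_table(rows), instruments = instruments,
       latent = latent)
}
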