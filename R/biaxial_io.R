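# Raw biaxial recordings -> Piola stress-stretch curves, cycle extraction,
# resampling/averaging, and the long-format dataset dialect used throughout
# the package.

.MODES <- c("strip-x", "strip-y", "off-x", "off-y", "equibiax")
.DIRECTIONS <- c("x", "y")

#' Loading modes of the biaxial protocol
#'
#' The five stretch-ratio modes of the testing protocol: `strip-x` and
#' `strip-y` hold one axis at `lambda = 1`, `off-x` and `off-y` stretch both
#' axes with one leading, and `equibiax` stretches both equally.
#'
#' @return Character vector of the five mode labels.
#' @export
biaxial_modes <- function() .MODES

# Direction whose stretch drives a mode (the "leading" channel used as the
# resampling abscissa); for equibiax both move together and x is used.
leading_direction <- function(mode) {
  switch(mode,
         "strip-x" = "x", "off-x" = "x", "equibiax" = "x",
         "strip-y" = "y", "off-y" = "y",
         stop("unknown mode: ", mode, call. = FALSE))
}

# The held channel of a strip mode ("x" direction of strip-y is held at 1),
# or NA for modes where both directions are stretched.
hold_direction <- function(mode) {
  switch(mode, "strip-x" = "y", "strip-y" = "x", NA_character_)
}

is_hold_channel <- function(mode, direction) {
  !is.na(hd <- vapply(mode, hold_direction, character(1))) & direction == hd
}

#' Test protocol description
#'
#' Parameters of the biaxial stretch protocol: preload used to define the
#' reference gauge lengths, quasi-static stretch rate, target stretch, number
#' of stretch-recovery cycles, and the order in which the five modes are run.
#'
#' @param preload preload force in mN applied along both axes before a test;
#'   the reference configuration is taken where both forces first reach it.
#' @param stretch_rate stretch increase per second (fraction).
#' @param max_stretch target stretch of the leading axis (1.10 by default;
#'   1.25 is used for prosciutto-style products that tolerate more strain).
#' @param cycles stretch-recovery cycles per mode.
#' @param mode_order order of the five modes.
#' @return A list of class `test_protocol`.
#' @export
test_protocol <- function(preload = 30, stretch_rate = 0.01,
                          max_stretch = 1.10, cycles = 3,
                          mode_order = c("strip-y", "off-y", "equibiax",
                                         "off-x", "strip-x")) {
  stopifnot(preload >= 0, stretch_rate > 0, max_stretch > 1, cycles >= 1,
            all(mode_order %in% .MODES))
  structure(list(preload = preload, stretch_rate = stretch_rate,
                 max_stretch = max_stretch, cycles = cycles,
                 mode_order = mode_order),
            class = "test_protocol")
}

#' Raw biaxial recording
#'
#' One recording = one sample tested in one loading mode: time series of the
#' two axial forces (mN) and tine-to-tine gauge lengths (mm), plus the sample
#' thickness (mm) and the mode label.
#'
#' @param time time in seconds, strictly increasing.
#' @param force_x,force_y measured forces in mN.
#' @param gauge_x,gauge_y measured gauge lengths in mm, positive.
#' @param thickness sample thickness in mm, positive.
#' @param mode one of [biaxial_modes()].
#' @param sample_id optional identifier.
#' @return An object of class `biaxial_recording` (a list with a `data`
#'   data frame and metadata fields).
#' @export
biaxial_recording <- function(time, force_x, force_y, gauge_x, gauge_y,
                              thickness, mode, sample_id = NA_character_) {
  n <- length(time)
  if (!all(lengths(list(force_x, force_y, gauge_x, gauge_y)) == n))
    stop("force and gauge series must have the same length as time",
         call. = FALSE)
  if (n < 2 || any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(gauge_x <= 0) || any(gauge_y <= 0))
    stop("gauge lengths must be positive", call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1 || thickness <= 0)
    stop("thickness must be a single positive number (mm)", call. = FALSE)
  mode <- match.arg(mode, .MODES)
  structure(list(data = data.frame(time = time, force_x = force_x,
                                   force_y = force_y, gauge_x = gauge_x,
                                   gauge_y = gauge_y),
                 thickness = thickness, mode = mode, sample_id = sample_id),
            class = "biaxial_recording")
}

#' @export
print.biaxial_recording <- function(x, ...) {
  cat(sprintf("Biaxial recording: mode %s, %d steps, thickness %.3g mm\n",
              x$mode, nrow(x$data), x$thickness))
  invisible(x)
}

#' Reference gauge lengths from the preload condition
#'
#' Scans the recording for the first time step at which both measured forces
#' have reached the protocol preload and returns the gauge lengths at that
#' step. These define the reference configuration for stretch and stress.
#'
#' @param recording a [biaxial_recording()].
#' @param protocol a [test_protocol()]; only `preload` is used.
#' @return Named numeric vector `c(L1 = , L2 = )` in mm.
#' @export
set_gauge_reference <- function(recording, protocol = test_protocol()) {
  stopifnot(inherits(recording, "biaxial_recording"))
  d <- recording$data
  hit <- which(d$force_x >= protocol$preload & d$force_y >= protocol$preload)
  if (!length(hit))
    stop(sprintf(paste0("unusable recording: forces never reach the ",
                        "preload of %g mN on both axes"), protocol$preload),
         call. = FALSE)
  i <- hit[1]
  c(L1 = d$gauge_x[i], L2 = d$gauge_y[i])
}

#' Convert a recording to stretches and Piola stresses
#'
#' With reference gauge lengths `L1`, `L2` (mm), thickness `t` (mm) and
#' forces in mN, the stretches and Piola stresses are
#' `lambda1 = l1/L1`, `lambda2 = l2/L2`, `P11 = F1/(L2 t)`, `P22 = F2/(L1 t)`,
#' and the mN/mm unit system delivers stresses directly in kPa.
#'
#' @param recording a [biaxial_recording()].
#' @param reference named vector `c(L1, L2)` from [set_gauge_reference()].
#' @return A data frame of class `biax_curves` with columns `time`,
#'   `lambda1`, `lambda2`, `P11`, `P22` and attributes `mode`, `thickness`.
#' @export
to_stretch_stress <- function(recording, reference) {
  stopifnot(inherits(recording, "biaxial_recording"))
  if (length(reference) != 2 || any(!is.finite(reference)) ||
      any(reference <= 0))
    stop("reference lengths must be two positive numbers (mm)",
         call. = FALSE)
  L1 <- reference[[1]]; L2 <- reference[[2]]
  t <- recording$thickness
  d <- recording$data
  out <- data.frame(time = d$time,
                    lambda1 = d$gauge_x / L1,
                    lambda2 = d$gauge_y / L2,
                    P11 = d$force_x / (L2 * t),
                    P22 = d$force_y / (L1 * t))
  structure(out, mode = recording$mode, thickness = t,
            class = c("biax_curves", "data.frame"))
}

# Split an increasing/decreasing signal into monotone runs. Returns an
# integer run id per *point*; the turning point is shared between the runs it
# joins. Zero increments are merged into the preceding run.
monotone_runs <- function(signal) {
  s <- sign(diff(signal))
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  r <- rle(s)
  list(sign = r$values,
       start = cumsum(c(1, r$lengths[-length(r$lengths)])),
       end = cumsum(r$lengths) + 1)
}

#' Extract one stretch-recovery cycle from a recording or curve set
#'
#' Segments the leading-direction signal (gauge length for recordings,
#' stretch for converted curves) into ascending and descending runs. The
#' k-th ascending run is the loading phase of cycle k, the k-th descending
#' run its unloading phase. The turning point at peak stretch belongs to
#' both phases.
#'
#' @param x a [biaxial_recording()] or a `biax_curves` data frame from
#'   [to_stretch_stress()].
#' @param cycle_index which cycle, 1-based.
#' @param phase `"loading"` or `"unloading"`.
#' @return Object of the same class as `x`, restricted to the requested
#'   phase of the requested cycle.
#' @export
extract_cycle <- function(x, cycle_index, phase = c("loading", "unloading")) {
  phase <- match.arg(phase)
  UseMethod("extract_cycle")
}

cycle_rows <- function(signal, cycle_index, phase) {
  runs <- monotone_runs(signal)
  want <- if (phase == "loading") 1 else -1
  idx <- which(runs$sign == want)
  if (cycle_index > length(idx))
    stop(sprintf("cycle %d (%s) not present: only %d such runs found",
                 cycle_index, phase, length(idx)), call. = FALSE)
  i <- idx[cycle_index]
  seq(runs$start[i], runs$end[i])
}

#' @export
extract_cycle.biaxial_recording <- function(x, cycle_index,
                                            phase = c("loading",
                                                      "unloading")) {
  phase <- match.arg(phase)
  lead <- leading_direction(x$mode)
  signal <- if (lead == "x") x$data$gauge_x else x$data$gauge_y
  rows <- cycle_rows(signal, cycle_index, phase)
  out <- x
  out$data <- x$data[rows, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' @export
extract_cycle.biax_curves <- function(x, cycle_index,
                                      phase = c("loading", "unloading")) {
  phase <- match.arg(phase)
  lead <- leading_direction(attr(x, "mode"))
  signal <- if (lead == "x") x$lambda1 else x$lambda2
  rows <- cycle_rows(signal, cycle_index, phase)
  out <- x[rows, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("mode", "thickness", "class")] <-
    attributes(x)[c("mode", "thickness", "class")]
  out
}

#' Resample curves on a common stretch grid and average
#'
#' All curves (same mode; typically the loading and unloading halves of the
#' final cycle across several samples) are linearly interpolated onto a
#' common equidistant grid of the leading-direction stretch, running from 1
#' to the smallest shared maximum. Stresses and the trailing-direction
#' stretch are interpolated against the leading stretch and averaged
#' pointwise; the dispersion column holds the standard error across curves.
#'
#' By default the averaged curves are re-anchored so the first grid point is
#' exactly `lambda = 1`, `P = 0`: the (interpolated) stress at the grid
#' origin -- e.g. the preload offset -- is subtracted from each channel.
#'
#' @param curves list of `biax_curves` objects of the same mode.
#' @param n_points grid size; 11 mirrors the packaged mean dataset.
#' @param anchor subtract the first-grid-point stress from each channel.
#' @return A long-format data frame (columns `mode`, `direction`, `stretch`,
#'   `stress_kPa`, `stderr_kPa`, `hold`) with one row per grid point and
#'   direction; class `biax_data`.
#' @export
resample_and_average <- function(curves, n_points = 11, anchor = TRUE) {
  if (inherits(curves, "biax_curves")) curves <- list(curves)
  if (!length(curves) || !all(vapply(curves, inherits, TRUE, "biax_curves")))
    stop("curves must be a list of biax_curves objects", call. = FALSE)
  mode <- attr(curves[[1]], "mode")
  if (!all(vapply(curves, function(cv) identical(attr(cv, "mode"), mode),
                  TRUE)))
    stop("all curves must share the same loading mode", call. = FALSE)
  if (any(vapply(curves, nrow, 1L) < 2))
    stop("curves with a single point cannot be resampled", call. = FALSE)
  lead <- leading_direction(mode)
  lcol <- if (lead == "x") "lambda1" else "lambda2"
  lo <- max(vapply(curves, function(cv) min(cv[[lcol]]), 1))
  hi <- min(vapply(curves, function(cv) max(cv[[lcol]]), 1))
  if (hi <= lo)
    stop("curves have no overlapping stretch range", call. = FALSE)
  grid <- seq(max(1, lo), hi, length.out = n_points)

  chans <- c("lambda1", "lambda2", "P11", "P22")
  interped <- lapply(curves, function(cv) {
    o <- order(cv[[lcol]])
    vapply(chans, function(ch)
      stats::approx(cv[[lcol]][o], cv[[ch]][o], xout = grid, ties = mean)$y,
      numeric(n_points))
  })
  arr <- simplify2array(interped)             # n_points x 4 x n_curves
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  avg <- apply(arr, c(1, 2), mean)
  k <- dim(arr)[3]
  se <- if (k > 1) apply(arr, c(1, 2), stats::sd) / sqrt(k) else
    matrix(NA_real_, n_points, length(chans))
  colnames(avg) <- colnames(se) <- chans

  if (anchor) {
    avg[, "P11"] <- avg[, "P11"] - avg[1, "P11"]
    avg[, "P22"] <- avg[, "P22"] - avg[1, "P22"]
    avg[1, lcol] <- 1
  }
  out <- rbind(
    data.frame(mode = mode, direction = "x", stretch = avg[, "lambda1"],
               stress_kPa = avg[, "P11"], stderr_kPa = se[, "P11"]),
    data.frame(mode = mode, direction = "y", stretch = avg[, "lambda2"],
               stress_kPa = avg[, "P22"], stderr_kPa = se[, "P22"]))
  out$hold <- is_hold_channel(out$mode, out$direction)
  rownames(out) <- NULL
  structure(out, class = c("biax_data", "data.frame"))
}

#' Validate a long-format biaxial dataset
#'
#' The package exchanges stress-stretch data as a long data frame with
#' columns `mode`, `direction`, `stretch`, `stress_kPa`, and optionally
#' `product`, `stderr_kPa`. A logical `hold` column flagging the held
#' channels of the strip modes is added if absent.
#'
#' @param data a data frame in the dialect above.
#' @return The validated data frame with class `biax_data`.
#' @export
as_biax_data <- function(data) {
  need <- c("mode", "direction", "stretch", "stress_kPa")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!data$mode %in% .MODES)
  if (length(bad))
    stop("unknown mode at row ", bad[1], ": ", data$mode[bad[1]],
         call. = FALSE)
  bad <- which(!data$direction %in% .DIRECTIONS)
  if (length(bad))
    stop("unknown direction at row ", bad[1], ": ", data$direction[bad[1]],
         call. = FALSE)
  for (col in c("stretch", "stress_kPa")) {
    if (!is.numeric(data[[col]]))
      stop("column ", col, " must be numeric", call. = FALSE)
    bad <- which(!is.finite(data[[col]]))
    if (length(bad))
      stop("non-finite ", col, " at row ", bad[1], call. = FALSE)
  }
  if (any(data$stretch <= 0))
    stop("stretches must be positive", call. = FALSE)
  if (is.null(data$hold))
    data$hold <- is_hold_channel(data$mode, data$direction)
  class(data) <- unique(c("biax_data", class(data)))
  data
}

#' Read / write a biaxial dataset
#'
#' `load_dataset()` reads a delimited long-format dataset (header
#' `product,mode,direction,stretch,stress_kPa[,stderr_kPa]`) and validates
#' it; `save_dataset()` writes one. The round trip is the identity up to
#' float formatting.
#'
#' @param path file path.
#' @return `load_dataset()` returns a `biax_data` data frame.
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(raw)) stop("empty dataset: ", path, call. = FALSE)
  as_biax_data(raw)
}

#' @rdname load_dataset
#' @param data a `biax_data` data frame.
#' @export
save_dataset <- function(data, path) {
  data <- as_biax_data(data)
  cols <- intersect(c("product", "mode", "direction", "stretch",
                      "stress_kPa", "stderr_kPa"), names(data))
  utils::write.csv(data[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged mean biaxial dataset for eight deli products
#'
#' Mean Piola stress-stretch data for four plant-based (PT, PH, PD, PP) and
#' four animal (AT, AH, AC, AP) commercial deli meats: five loading modes,
#' both directions, eleven points per mode, loading/unloading averaged over
#' n = 8 samples per product.
#'
#' @param product optional product id(s) to subset to.
#' @return A `biax_data` data frame with a `product` column.
#' @examples
#' d <- deli_meat_means("PT")
#' table(d$mode, d$direction)
#' @export
deli_meat_means <- function(product = NULL) {
  path <- system.file("extdata", "deli_biaxial_means.csv",
                      package = "delimech", mustWork = TRUE)
  d <- load_dataset(path)
  if (!is.null(product)) {
    bad <- setdiff(product, unique(d$product))
    if (length(bad))
      stop("unknown product id: ", paste(bad, collapse = ", "),
           call. = FALSE)
    d <- d[d$product %in% product, , drop = FALSE]
    rownames(d) <- NULL
    class(d) <- unique(c("biax_data", class(d)))
  }
  d
}

#' Read a raw recording with its sidecar configuration
#'
#' The raw file is delimited text with header
#' `time_s,force_x_mN,force_y_mN,gauge_x_mm,gauge_y_mm`; the sidecar is a
#' small YAML file carrying `thickness_mm`, `mode_label`, optionally
#' `sample_id` and protocol overrides.
#'
#' @param path path to the raw delimited file.
#' @param sidecar path to the YAML sidecar; defaults to `<path>.yml`.
#' @return A list with elements `recording` ([biaxial_recording()]) and
#'   `protocol` ([test_protocol()]).
#' @export
read_raw_recording <- function(path, sidecar = paste0(path, ".yml")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "force_x_mN", "force_y_mN", "gauge_x_mm", "gauge_y_mm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("raw recording is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!file.exists(sidecar))
    stop("sidecar configuration not found: ", sidecar, call. = FALSE)
  cfg <- yaml::read_yaml(sidecar)
  if (is.null(cfg$thickness_mm) || is.null(cfg$mode_label))
    stop("sidecar must provide thickness_mm and mode_label", call. = FALSE)
  proto_args <- cfg$protocol %||% list()
  rec <- biaxial_recording(d$time_s, d$force_x_mN, d$force_y_mN,
                           d$gauge_x_mm, d$gauge_y_mm,
                           thickness = cfg$thickness_mm,
                           mode = cfg$mode_label,
                           sample_id = cfg$sample_id %||% NA_character_)
  list(recording = rec, protocol = do.call(test_protocol, proto_args))
}

#' @rdname read_raw_recording
#' @param recording a [biaxial_recording()] to write.
#' @param protocol optional [test_protocol()] stored in the sidecar.
#' @export
write_raw_recording <- function(recording, path,
                                sidecar = paste0(path, ".yml"),
                                protocol = NULL) {
  stopifnot(inherits(recording, "biaxial_recording"))
  d <- recording$data
  names(d) <- c("time_s", "force_x_mN", "force_y_mN", "gauge_x_mm",
                "gauge_y_mm")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  cfg <- list(thickness_mm = recording$thickness,
              mode_label = recording$mode,
              sample_id = recording$sample_id)
  if (!is.null(protocol)) cfg$protocol <- unclass(protocol)
  yaml::write_yaml(cfg, sidecar)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
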