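test_that("stretch/stress conversion implements the gauge-area formulas", {
  n <- 5
  rec <- biaxial_recording(time = 1:n, force_x = rep(144, n),
                           force_y = rep(0, n), gauge_x = rep(12, n),
                           gauge_y = rep(12, n), thickness = 1,
                           mode = "strip-x")
  cv <- to_stretch_stress(rec, c(L1 = 12, L2 = 12))
  expect_equal(cv$P11, rep(12, n))          # 144 mN / (12 mm * 1 mm) = 12 kPa
  expect_equal(cv$P22, rep(0, n))           # zero force, zero stress
  expect_equal(cv$lambda1, rep(1, n))       # l1 = L1 throughout

  # dimensional property: mN and mm in, kPa out, for random positive inputs
  set.seed(5)
  for (rep in 1:10) {
    L <- runif(2, 8, 15); t <- runif(1, 0.5, 1.5)
    F1 <- runif(n, 0, 300); F2 <- runif(n, 0, 300)
    l1 <- runif(n, 0.9, 1.3) * L[1]
    rec <- biaxial_recording(1:n, F1, F2, sort(l1), rep(L[2], n), t,
                             mode = "off-x")
    cv <- to_stretch_stress(rec, c(L1 = L[1], L2 = L[2]))
    expect_equal(cv$P11, F1 / (L[2] * t))
    expect_equal(cv$P22, F2 / (L[1] * t))
  }
})

test_that("recording construction and conversion reject invalid inputs", {
  expect_error(biaxial_recording(1:3, 1:3, 1:3, 1:3, 1:3, thickness = 0,
                                 mode = "equibiax"), "thickness")
  expect_error(biaxial_recording(c(1, 1, 2), 1:3, 1:3, 1:3, 1:3, 1,
                                 mode = "equibiax"), "increasing")
  expect_error(biaxial_recording(1:3, 1:2, 1:3, 1:3, 1:3, 1,
                                 mode = "equibiax"), "length")
  rec <- triangle_recording()
  expect_error(to_stretch_stress(rec, c(0, 12)), "positive")
})

test_that("gauge reference is the first step at which both forces reach the preload", {
  n <- 10
  rec <- biaxial_recording(time = 1:n, force_x = seq(0, 90, length.out = n),
                           force_y = seq(0, 45, length.out = n),
                           gauge_x = seq(11, 12.8, length.out = n),
                           gauge_y = seq(11, 12.8, length.out = n),
                           thickness = 1, mode = "equibiax")
  # linear-scan oracle
  fx <- seq(0, 90, length.out = n); fy <- seq(0, 45, length.out = n)
  k <- which(fx >= 30 & fy >= 30)[1]
  ref <- set_gauge_reference(rec, test_protocol(preload = 30))
  expect_equal(unname(ref), rep(seq(11, 12.8, length.out = n)[k], 2))

  # boundary: preload already satisfied at the first step
  ref0 <- set_gauge_reference(rec, test_protocol(preload = 0))
  expect_equal(unname(ref0), c(11, 11))

  expect_error(set_gauge_reference(rec, test_protocol(preload = 1000)),
               "preload")
})

test_that("cycle extraction partitions triangular records and picks the
           requested ramp", {
  rec <- triangle_recording(cycles = 1, n_ramp = 10)
  ld <- extract_cycle(rec, 1, "loading")
  ul <- extract_cycle(rec, 1, "unloading")
  # halves share the peak point and jointly cover the record
  expect_equal(nrow(ld$data) + nrow(ul$data), nrow(rec$data) + 1)
  expect_true(all(diff(ld$data$gauge_x) > 0))
  expect_true(all(diff(ul$data$gauge_x) < 0))

  rec3 <- triangle_recording(cycles = 3, n_ramp = 10)
  ld3 <- extract_cycle(rec3, 3, "loading")
  expect_equal(nrow(ld3$data), 11)
  expect_equal(max(ld3$data$gauge_x), max(rec3$data$gauge_x))
  # the third ascending ramp is the last 21..11 rows before the final descent
  expect_error(extract_cycle(rec3, 4, "loading"), "not present")

  # strip mode: held channel returns with lambda = 1 throughout
  recs <- triangle_recording(cycles = 1, mode = "strip-x", n_ramp = 10)
  cv <- to_stretch_stress(recs, c(12, 12))
  ldc <- extract_cycle(cv, 1, "loading")
  expect_true(all(ldc$lambda2 == 1))
})

test_that("conversion and cycle extraction commute", {
  rec <- triangle_recording(cycles = 3, n_ramp = 15)
  ref <- c(12, 12)
  a <- to_stretch_stress(extract_cycle(rec, 2, "unloading"), ref)
  b <- extract_cycle(to_stretch_stress(rec, ref), 2, "unloading")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("resampling averages curves linearly and is idempotent", {
  mk_curve <- function(fac, lam = seq(1, 1.1, length.out = 21)) {
    p <- nh_stress(50, lam, lam)
    structure(data.frame(time = seq_along(lam), lambda1 = lam, lambda2 = lam,
                         P11 = p$P11 * fac, P22 = p$P22 * fac),
              mode = "equibiax", class = c("biax_curves", "data.frame"))
  }
  # linearity: average of s and 3s is 2s
  avg <- resample_and_average(list(mk_curve(1), mk_curve(3)), n_points = 11)
  one <- resample_and_average(list(mk_curve(2)), n_points = 11)
  expect_equal(avg$stress_kPa, one$stress_kPa, tolerance = 1e-12)

  # single curve on its own grid: interpolated copy (identity)
  lam11 <- seq(1, 1.1, length.out = 11)
  c11 <- mk_curve(1, lam11)
  out <- resample_and_average(list(c11), n_points = 11)
  expect_equal(out$stress_kPa[out$direction == "x"], c11$P11,
               tolerance = 1e-12)
  # idempotence: resampling the resampled curve changes nothing
  back <- structure(data.frame(time = 1:11, lambda1 = lam11, lambda2 = lam11,
                               P11 = out$stress_kPa[out$direction == "x"],
                               P22 = out$stress_kPa[out$direction == "y"]),
                    mode = "equibiax", class = c("biax_curves", "data.frame"))
  again <- resample_and_average(list(back), n_points = 11)
  expect_equal(again$stress_kPa, out$stress_kPa, tolerance = 1e-12)

  # symmetric +-10% hysteresis averages back to the elastic midline
  up <- mk_curve(1.1)
  dn <- mk_curve(0.9)
  dn <- dn[rev(seq_len(nrow(dn))), ]       # recorded in descending order
  attributes(dn)[c("mode", "class")] <- attributes(up)[c("mode", "class")]
  mid <- resample_and_average(list(up, dn), n_points = 11)
  elastic <- nh_stress(50, lam11, lam11)
  expect_equal(mid$stress_kPa[mid$direction == "x"], elastic$P11,
               tolerance = 1e-8)

  expect_error(resample_and_average(list(mk_curve(1, seq(1, 1.05, length.out = 5)),
                                         mk_curve(1, seq(1.2, 1.25, length.out = 5)))),
               "overlap")
})

test_that("dataset round trip preserves values and the packaged data parse", {
  d <- closed_form_dataset(60, -10)
  d$product <- "SYN"
  path <- tempfile(fileext = ".csv")
  save_dataset(d, path)
  back <- load_dataset(path)
  expect_equal(back$stress_kPa, d$stress_kPa, tolerance = 1e-9)
  expect_equal(back$stretch, d$stretch, tolerance = 1e-9)
  expect_equal(back$mode, d$mode)

  # malformed inputs fail with informative errors
  empty <- tempfile(fileext = ".csv")
  writeLines("product,mode,direction,stretch,stress_kPa", empty)
  expect_error(load_dataset(empty), "empty")
  bad <- d; bad$mode[3] <- "twist"
  expect_error(as_biax_data(bad), "row 3")
})

test_that("packaged mean dataset has the documented layout", {
  d <- deli_meat_means()
  expect_equal(sort(unique(d$product)),
               sort(c("PT", "PH", "PD", "PP", "AT", "AH", "AC", "AP")))
  expect_equal(nrow(d), 8 * 5 * 2 * 11)
  counts <- table(d$product, d$mode, d$direction)
  expect_true(all(counts == 11))

  at <- deli_meat_means("AT")
  eq <- at[at$mode == "equibiax" & at$direction == "x", ]
  first_nonzero <- eq[eq$stress_kPa > 0, ][1, ]
  expect_equal(first_nonzero$stretch, 1.01)
  expect_equal(first_nonzero$stress_kPa, 2.29)
  # every curve starts anchored at lambda = 1, P = 0
  starts <- d[!duplicated(d[c("product", "mode", "direction")]), ]
  expect_true(all(starts$stretch == 1))
  expect_true(all(starts$stress_kPa == 0))
  expect_error(deli_meat_means("XX"), "unknown product")
})

test_that("raw recordings round-trip through file and sidecar", {
  rec <- triangle_recording(cycles = 2, n_ramp = 8)
  path <- tempfile(fileext = ".csv")
  write_raw_recording(rec, path, protocol = test_protocol(cycles = 2))
  got <- read_raw_recording(path)
  expect_equal(got$recording$data, rec$data, tolerance = 1e-9)
  expect_equal(got$recording$mode, rec$mode)
  expect_equal(got$recording$thickness, rec$thickness)
  expect_equal(got$protocol$cycles, 2)
})
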