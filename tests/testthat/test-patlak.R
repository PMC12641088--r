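test_that("Patlak transform reduces to t under constant plasma input", {
  times <- seq(0.5, 119.5, by = 1)
  ctv <- 0.3 * times + 2
  curve <- tac(times, cp = rep(4, 120), ct = ctv)
  p <- patlak_transform(curve)
  # int_0^t c dtau / c = t - t_0 from the first frame, in minutes
  expect_equal(p$xs, (times - times[1]) / 60, tolerance = 1e-12)
  expect_equal(p$ys, ctv / 4)
  # zero tissue activity -> flat zero ordinate
  p0 <- patlak_transform(tac(times, rep(4, 120), rep(0, 120)))
  expect_equal(p0$ys, rep(0, 120))
  # vanishing plasma inside the curve is an error naming the frame
  expect_error(patlak_transform(tac(1:5, c(1, 1, 0, 1, 1), rep(1, 5))),
               "frame\\(s\\) 3")
})

test_that("transform matches a fine-grid quadrature oracle for a gamma input", {
  a <- 3; b <- 20
  cp_fun <- function(t) t^a * exp(-t / b)
  times <- seq(0.5, 119.5, by = 1)
  curve <- tac(times, cp_fun(times), ct = 0.4 * cp_fun(times))
  p <- patlak_transform(curve)
  fine <- seq(times[1], times[length(times)], by = 0.005)
  fine_int <- c(0, cumsum(diff(fine) * (cp_fun(fine)[-1] +
                                          cp_fun(fine)[-length(fine)]) / 2))
  oracle_xs <- approx(fine, fine_int, xout = times)$y / cp_fun(times) / 60
  expect_lt(max(abs(p$xs - oracle_xs)) / diff(range(oracle_xs)), 1e-3)
})

test_that("Patlak fit recovers K1 and V0 exactly in the noiseless case", {
  curve <- gen_tac(k1 = 0.5, v0 = 0.2, noise_sd = 0)
  fit <- patlak_fit(curve)
  expect_equal(fit$k1, 0.5, tolerance = 1e-10)
  expect_equal(fit$v0, 0.2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # k1 = 0 collapses to ct = V0 * cp
  curve0 <- gen_tac(k1 = 0, v0 = 0.3, noise_sd = 0)
  expect_equal(curve0$ct, 0.3 * curve0$cp)
  fit0 <- patlak_fit(curve0)
  expect_equal(fit0$k1, 0, tolerance = 1e-12)
  expect_equal(fit0$v0, 0.3, tolerance = 1e-12)
})

test_that("Patlak fit is invariant to joint rescaling of cp and ct", {
  curve <- gen_tac(k1 = 0.4, v0 = 0.25, noise_sd = 0.01, seed = 2)
  scaled <- tac(curve$times, 3.7 * curve$cp, 3.7 * curve$ct)
  f1 <- patlak_fit(curve)
  f2 <- patlak_fit(scaled)
  expect_equal(f1$k1, f2$k1, tolerance = 1e-12)
  expect_equal(f1$v0, f2$v0, tolerance = 1e-12)
})

test_that("fit windows are validated", {
  curve <- gen_tac(k1 = 0.5, v0 = 0.2)
  expect_error(patlak_fit(curve, window = c(5, 6)), ">= 3 frames")
  expect_error(patlak_fit(curve, window = c(100, 150, 200)), "outside")
  explicit <- patlak_fit(curve, window = 60:120)
  expect_equal(explicit$k1, 0.5, tolerance = 1e-10)
  expect_match(explicit$window_rule, "explicit")
})

test_that("territory aggregation is the area-weighted mean", {
  template <- toy_roi_template(2)
  # constants aggregate to the constant
  v <- setNames(rep(47, nrow(template)), template$roi_id)
  agg <- aggregate_territories(v, template)
  expect_equal(agg$cbf_ml_100g_min, rep(47, 24))
  # forced arithmetic: values (50, 60) with areas (1, 3) -> 57.5
  t2 <- data.frame(roi_id = c("r1", "r2"), hemisphere = "left",
                   territory = "pericallosal", area = c(1, 3))
  one <- aggregate_territories(c(r1 = 50, r2 = 60), t2[1:2, ],
                               participant_id = "p")
  expect_equal(one$cbf_ml_100g_min[one$region == "pericallosal_left"], 57.5)
  # missing ROI values are reported
  expect_error(aggregate_territories(v[-1], template), template$roi_id[1])
})

test_that("aggregation equals a direct summation oracle and stays bounded", {
  set.seed(59)
  template <- toy_roi_template(3)
  template$area <- runif(nrow(template), 0.5, 3)
  v <- setNames(runif(nrow(template), 30, 70), template$roi_id)
  agg <- aggregate_territories(v, template)
  for (i in seq_len(nrow(agg))) {
    parts <- template$roi_id[paste(template$territory, template$hemisphere,
                                   sep = "_") == agg$region[i]]
    w <- template$area[match(parts, template$roi_id)]
    expect_equal(agg$cbf_ml_100g_min[i], sum(w * v[parts]) / sum(w))
    expect_gte(agg$cbf_ml_100g_min[i], min(v[parts]))
    expect_lte(agg$cbf_ml_100g_min[i], max(v[parts]))
  }
})

test_that("global count normalization divides by the area-weighted mean", {
  set.seed(61)
  template <- toy_roi_template(2)
  v <- setNames(runif(nrow(template), 30, 70), template$roi_id)
  raw <- aggregate_territories(v, template)
  norm <- aggregate_territories(v, template, global_normalize = TRUE)
  gm <- sum(template$area * v[template$roi_id]) / sum(template$area)
  expect_equal(norm$cbf_ml_100g_min, raw$cbf_ml_100g_min / gm)
})
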