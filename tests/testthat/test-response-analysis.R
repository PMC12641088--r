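std_x <- standard_scores_nd()$mean_score

test_that("standard response reproduces the pivotal 'now' anchor", {
  # every ND participant scores sentence No. 5 (now) as the present
  df <- expand.grid(participant_id = paste0("nd", 1:6), sentence_id = 1:11,
                    stringsAsFactors = FALSE)
  df$group <- "ND"
  df$score <- ifelse(df$sentence_id == 5, 5,
                     sample(1:9, nrow(df), replace = TRUE))
  std <- compute_standard_response(validate_response_table(df))
  expect_equal(std$mean_score[std$sentence_id == 5], 5.0)
  expect_equal(std$sd_score[std$sentence_id == 5], 0)
})

test_that("standard response means/SDs equal a brute-force recomputation", {
  set.seed(21)
  mat <- matrix(sample(1:9, 66, replace = TRUE), nrow = 6)  # 6 ND x 11
  df <- data.frame(participant_id = rep(paste0("nd", 1:6), times = 11),
                   group = "ND",
                   sentence_id = rep(1:11, each = 6),
                   score = as.vector(mat))
  std <- compute_standard_response(validate_response_table(df))
  for (s in 1:11) {
    v <- mat[, s]
    expect_equal(std$mean_score[std$sentence_id == s], sum(v) / 6)
    expect_equal(std$sd_score[std$sentence_id == s],
                 sqrt(sum((v - mean(v))^2) / 5))
  }
  # ascending sort is a permutation of 1..11
  expect_setequal(std$sentence_id, 1:11)
  expect_true(!is.unsorted(std$mean_score))
})

test_that("single-participant standard response reports SD 0 with a flag", {
  df <- data.frame(participant_id = "nd1", group = "ND",
                   sentence_id = 1:11, score = c(2:9, 7, 5, 3))
  std <- suppressMessages(compute_standard_response(validate_response_table(df)))
  expect_equal(std$mean_score[order(std$sentence_id)],
               as.numeric(c(2:9, 7, 5, 3)))
  expect_true(all(std$sd_score == 0))
  expect_true(all(std$sd_flagged))
})

test_that("pivotal fit matches closed form and a grid-search minimizer", {
  # exact line through the pivot
  y2 <- 2 * (std_x - 5) + 5
  f <- fit_pivotal(std_x, y2)
  expect_equal(f$slope, 2)
  expect_equal(f$dc, 1)

  # worked example: x = 3..7, y = (4,4,5,6,8) has slope exactly 1
  x <- 3:7; y <- c(4, 4, 5, 6, 8)
  f2 <- fit_pivotal(x, y)
  expect_equal(f2$slope, 1.0)
  expect_lt(abs(f2$slope - oracle_pivotal_slope(x, y)), 1e-4)
  ss_res <- sum((y - (f2$slope * (x - 5) + 5))^2)
  expect_equal(f2$dc_raw, 1 - ss_res / sum((y - mean(y))^2))

  # random cases agree with the dense grid search
  set.seed(31)
  for (rep in 1:5) {
    yr <- sample(1:9, 11, replace = TRUE)
    fr <- fit_pivotal(std_x, yr)
    # the grid oracle resolves the minimizer to half its step
    expect_lt(abs(fr$slope - oracle_pivotal_slope(std_x, yr)), 1e-4)
  }
})

test_that("pivotal fit flags degenerate designs and constant responses", {
  expect_error(fit_pivotal(rep(5, 11), 1:11), "degenerate")
  f <- fit_pivotal(std_x, rep(7, 11))
  expect_false(f$dc_defined)
  expect_true(is.na(f$dc))
  expect_true(is.finite(f$slope))
})

test_that("d.c. is 1 exactly when residuals vanish for non-constant y", {
  set.seed(41)
  for (k in c(-1, 0.5, 2)) {
    y <- k * (std_x - 5) + 5
    expect_equal(fit_pivotal(std_x, y)$dc, 1)
    noisy <- y + rnorm(11, 0, 0.3)
    expect_lt(fit_pivotal(std_x, noisy)$dc, 1)
  }
})

test_that("pivotal fit is invariant to the ordering of sentence pairs", {
  set.seed(51)
  y <- sample(1:9, 11, replace = TRUE)
  f1 <- fit_pivotal(std_x, y)
  perm <- sample(11)
  f2 <- fit_pivotal(std_x[perm], y[perm])
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$dc_raw, f2$dc_raw)
})

test_that("slope recovery from noisy pivotal lines is unbiased and tight", {
  # |k_hat - k| <= 0.05 on average at noise SD 0.25 over 200 replicates
  set.seed(61)
  for (k in c(0.5, 1, 2)) {
    err <- replicate(200, {
      y <- k * (std_x - 5) + 5 + rnorm(11, 0, 0.25)
      abs(fit_pivotal(std_x, y)$slope - k)
    })
    expect_lte(mean(err), 0.05)
  }
})

test_that("feature extraction equals per-participant fits and logs exclusions", {
  std <- standard_scores_nd()
  # cohort answering exactly the standard scores (rounded) -> slope ~ 1
  sim <- gen_responses(cohort_spec(n_regime1 = 6, n_regime2 = 0,
                                   n_regime3 = 0, slope_sd1 = 0,
                                   noise_sd1 = 0, seed = 3))
  feats <- suppressMessages(extract_features(sim$responses, std))
  expect_true(all(feats$included))
  # discretization of the standard scores is the only deviation
  expect_true(all(abs(feats$slope - 1) < 0.1))
  expect_true(all(feats$dc > 0.9))

  # elementwise equivalence with independent fit_pivotal calls
  sim2 <- gen_responses(cohort_spec(n_regime1 = 4, n_regime2 = 4,
                                    n_regime3 = 4, seed = 5))
  feats2 <- suppressMessages(extract_features(sim2$responses, std))
  xmap <- setNames(std$mean_score, std$sentence_id)
  for (pid in feats2$participant_id) {
    rows <- sim2$responses[sim2$responses$participant_id == pid, ]
    f <- fit_pivotal(xmap[as.character(rows$sentence_id)], rows$score)
    expect_equal(feats2$slope[feats2$participant_id == pid], f$slope)
    expect_equal(feats2$dc[feats2$participant_id == pid], f$dc)
  }
})

test_that("flat responders and incomplete participants are excluded", {
  df <- rbind(
    data.frame(participant_id = "flat", sentence_id = 1:11, score = 5),
    data.frame(participant_id = "partial", sentence_id = 1:7,
               score = c(2, 6, 3, 6, 5, 4, 2)),
    data.frame(participant_id = "ok", sentence_id = 1:11,
               score = c(7, 6, 4, 6, 5, 4, 2, 7, 6, 3, 4)))
  tab <- suppressMessages(validate_response_table(df))
  feats <- suppressMessages(extract_features(tab, standard_scores_nd()))
  expect_equal(feats$included[match(c("flat", "partial", "ok"),
                                    feats$participant_id)],
               c(FALSE, FALSE, TRUE))
  expect_match(feats$excluded_reason[feats$participant_id == "flat"],
               "constant")
  expect_match(feats$excluded_reason[feats$participant_id == "partial"],
               "incomplete")
  expect_equal(feats$slope[feats$participant_id == "flat"], 0)
  expect_error(extract_features(df[0, ], standard_scores_nd()), "empty")
})
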