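# round half away from zero, then clip to the nine-point scale
discretize_score <- function(x) {
  pmin(pmax(sign(x) * floor(abs(x) + 0.5), 1), 9)
}

#' Specification of a synthetic response cohort
#'
#' Encodes the three response regimes the cohort emulates:
#' \describe{
#'   \item{regime 1}{near-linear responders — per-participant slope
#'     drawn around 1 with small item noise (the intact pattern);}
#'   \item{regime 2}{coarse graders — every sentence is scored by its
#'     judged temporal category alone, far past 1 / present 5 / far
#'     future 9, with small per-item scatter around those targets and an
#'     optional random category flip (steep slopes > 1.5 against the
#'     standard scores, fair linearity);}
#'   \item{regime 3}{flat responders — scores hover near the pivot with
#'     only weak dependence on the sentence (slopes < 1, low explained
#'     variance).}
#' }
#' Item noise defaults sit in the range of the reference per-sentence
#' SDs of the non-demented group (0.41-0.75).
#'
#' @param n_regime1,n_regime2,n_regime3 participants per regime
#'   (default 20 / 15 / 20).
#' @param slope_mean1,slope_sd1 regime-1 slope distribution (1.0, 0.1).
#' @param noise_sd1 regime-1 item noise SD on the nine-point scale (0.5).
#' @param noise_sd2 regime-2 per-item scatter SD around the coarse
#'   1/5/9 targets (0.6).
#' @param flip_prob2 regime-2 probability that a sentence's coarse
#'   score is replaced by a random draw from \{1, 5, 9\} (0 by
#'   default; a stress dial, not part of the reference conditions).
#' @param slope_mean3,slope_sd3 regime-3 weak slope (0.15, 0.05).
#' @param noise_sd3 regime-3 item noise SD (0.8).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regime1 = 20L, n_regime2 = 15L, n_regime3 = 20L,
                        slope_mean1 = 1.0, slope_sd1 = 0.1, noise_sd1 = 0.5,
                        noise_sd2 = 0.6, flip_prob2 = 0,
                        slope_mean3 = 0.15, slope_sd3 = 0.05, noise_sd3 = 0.8,
                        seed = 1L) {
  spec <- as.list(environment())
  if (flip_prob2 < 0 || flip_prob2 > 1) abort("flip_prob2 must be in [0, 1]")
  if (any(c(noise_sd1, noise_sd2, noise_sd3, slope_sd1, slope_sd3) < 0)) {
    abort("noise and slope SDs must be >= 0")
  }
  if (any(c(n_regime1, n_regime2, n_regime3) < 0)) abort("n must be >= 0")
  class(spec) <- "cohort_spec"
  spec
}

# deterministic clinical-group composition per regime, mirroring the
# observed cluster make-up (regime 1 mixes ND/MCI/AD, regimes 2-3 are
# MCI/AD only)
regime_groups <- function(regime, n) {
  prop <- switch(regime,
                 `1` = c(ND = 10, MCI = 5, AD = 7) / 22,
                 `2` = c(ND = 0, MCI = 3, AD = 11) / 14,
                 `3` = c(ND = 0, MCI = 2, AD = 19) / 21)
  counts <- diff(c(0, round(cumsum(prop * n))))
  rep(names(prop), counts)
}

#' Generate a synthetic response cohort
#'
#' Draws integer nine-point scores for every participant and sentence
#' under the three regimes of a [cohort_spec()], against the given
#' standard scores (the regression abscissa). Scores are rounded half
#' away from zero and clipped to \[1, 9\]. Cluster-conditional MMSE and
#' total response time are attached as metadata. Pure function of
#' (spec, seed).
#'
#' @param spec a `cohort_spec`.
#' @param standard data.frame with `sentence_id`, `mean_score`
#'   (default [standard_scores_nd()]).
#' @return list: `responses` (a `response_table` with group, mmse and
#'   response_time_s columns) and `truth` (data.frame participant_id /
#'   regime / group).
#' @export
gen_responses <- function(spec, standard = standard_scores_nd()) {
  stopifnot(inherits(spec, "cohort_spec"))
  meta <- sentence_metadata()
  x <- stats::setNames(standard$mean_score, standard$sentence_id)
  sentence_ids <- as.integer(names(x))
  category <- meta$category[match(sentence_ids, meta$sentence_id)]
  coarse <- c(past = 1, present = 5, future = 9)[category]
  mmse_par <- list(`1` = c(26.5, 3.4), `2` = c(22.5, 2.3), `3` = c(19.8, 3.5))
  rt_par <- list(`1` = c(152.6, 75.8), `2` = c(277.3, 137.6),
                 `3` = c(416.0, 177.7))
  with_seed(spec$seed, {
    rows <- list()
    truth <- list()
    counter <- 0L
    for (regime in 1:3) {
      n <- spec[[paste0("n_regime", regime)]]
      if (n == 0L) next
      groups <- regime_groups(as.character(regime), n)
      for (j in seq_len(n)) {
        counter <- counter + 1L
        pid <- sprintf("S%03d", counter)
        y <- switch(as.character(regime),
          `1` = {
            k <- stats::rnorm(1, spec$slope_mean1, spec$slope_sd1)
            k * (x - 5) + 5 + stats::rnorm(length(x), 0, spec$noise_sd1)
          },
          `2` = {
            s <- coarse + stats::rnorm(length(coarse), 0, spec$noise_sd2)
            flip <- stats::runif(length(s)) < spec$flip_prob2
            s[flip] <- sample(c(1, 5, 9), sum(flip), replace = TRUE)
            s
          },
          `3` = {
            k <- stats::rnorm(1, spec$slope_mean3, spec$slope_sd3)
            k * (x - 5) + 5 + stats::rnorm(length(x), 0, spec$noise_sd3)
          })
        mmse <- round(min(max(stats::rnorm(1, mmse_par[[regime]][1],
                                           mmse_par[[regime]][2]), 0), 30))
        rt <- max(stats::rnorm(1, rt_par[[regime]][1], rt_par[[regime]][2]), 30)
        rows[[counter]] <- data.frame(
          participant_id = pid, group = groups[j],
          sentence_id = sentence_ids, score = discretize_score(y),
          mmse = mmse, response_time_s = round(rt, 1),
          stringsAsFactors = FALSE)
        truth[[counter]] <- data.frame(participant_id = pid,
                                       regime = regime, group = groups[j],
                                       stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) {
      empty <- data.frame(participant_id = character(), group = character(),
                          sentence_id = integer(), score = integer(),
                          mmse = integer(), response_time_s = numeric())
      list(responses = structure(empty,
                                 class = c("response_table", "data.frame")),
           truth = data.frame(participant_id = character(),
                              regime = integer(), group = character()))
    } else {
      list(responses = validate_response_table(do.call(rbind, rows)),
           truth = do.call(rbind, truth))
    }
  })
}

#' Specification of synthetic territory CBF
#'
#' Per-region Gaussian CBF with cluster-dependent mean decrements:
#' cluster 1 sits at baseline, clusters 2 and 3 are progressively
#' lower everywhere, and the bilateral pericallosal territories carry a
#' doubled decrement so they separate the clusters most strongly.
#'
#' @param baseline_mean baseline CBF mean, ml/100 g/min (default 50),
#'   a scalar or named vector over the 24 regions.
#' @param baseline_sd within-cluster SD (default 4).
#' @param decrement2,decrement3 mean decrement of clusters 2 / 3
#'   relative to cluster 1 in ordinary regions (3, 6).
#' @param pericallosal_factor multiplier on the decrements in
#'   pericallosal_right / pericallosal_left (default 2).
#' @param seed integer seed.
#' @return list of class `cbf_spec` with the expanded per-region,
#'   per-cluster mean matrix in `$means`.
#' @export
cbf_spec <- function(baseline_mean = 50, baseline_sd = 4,
                     decrement2 = 3, decrement3 = 6,
                     pericallosal_factor = 2, seed = 1L) {
  regions <- territory_names()
  base <- if (length(baseline_mean) == 1L) {
    stats::setNames(rep(baseline_mean, length(regions)), regions)
  } else {
    stopifnot(setequal(names(baseline_mean), regions))
    baseline_mean[regions]
  }
  fac <- ifelse(grepl("^pericallosal_", regions), pericallosal_factor, 1)
  means <- cbind(cluster1 = base,
                 cluster2 = base - decrement2 * fac,
                 cluster3 = base - decrement3 * fac)
  if (any(means <= 0)) {
    abort("cluster decrements drive some region means non-positive")
  }
  structure(list(baseline_mean = base, baseline_sd = baseline_sd,
                 decrement2 = decrement2, decrement3 = decrement3,
                 pericallosal_factor = pericallosal_factor,
                 means = means, seed = as.integer(seed)),
            class = "cbf_spec")
}

#' Generate synthetic territory CBF for a labelled cohort
#'
#' @param labels integer cluster (1-3) per participant, named by
#'   participant id.
#' @param spec a `cbf_spec`.
#' @return a `cbf_table` with 24 regions per participant.
#' @export
gen_cbf <- function(labels, spec) {
  stopifnot(inherits(spec, "cbf_spec"), !is.null(names(labels)),
            all(labels %in% 1:3))
  regions <- territory_names()
  with_seed(spec$seed, {
    rows <- lapply(names(labels), function(pid) {
      mu <- spec$means[, labels[[pid]]]
      data.frame(participant_id = pid, region = regions,
                 cbf_ml_100g_min = pmax(
                   stats::rnorm(length(regions), mu, spec$baseline_sd), 1),
                 stringsAsFactors = FALSE)
    })
    validate_cbf_table(do.call(rbind, rows))
  })
}

#' Generate a synthetic dynamic time-activity curve
#'
#' Gamma-variate plasma input (120 frames of 1 s, times at frame
#' midpoints) and a tissue curve from the irreversible two-compartment
#' model `ct = K1 * int cp + V0 * cp`, using the same trapezoidal
#' integral as the Patlak transform, plus optional Gaussian noise
#' scaled to the noiseless tissue maximum.
#'
#' @param k1 influx constant, 1/min (>= 0).
#' @param v0 initial distribution volume, dimensionless (>= 0).
#' @param noise_sd tissue noise SD as a fraction of max(ct) (e.g. 0.01).
#' @param seed integer seed.
#' @param n_frames number of 1-s frames (default 120).
#' @param alpha,beta gamma-variate shape and scale of the plasma input
#'   (default 3, 20 s); peak plasma activity is scaled to 100.
#' @return a `tac`.
#' @export
gen_tac <- function(k1, v0, noise_sd = 0, seed = 1L, n_frames = 120L,
                    alpha = 3, beta = 20) {
  stopifnot(k1 >= 0, v0 >= 0, noise_sd >= 0)
  times <- seq_len(n_frames) - 0.5
  peak <- (alpha * beta)^alpha * exp(-alpha)
  cp <- 100 * times^alpha * exp(-times / beta) / peak
  ct0 <- (k1 / 60) * cumtrapz(times, cp) + v0 * cp
  ct <- if (noise_sd > 0) {
    with_seed(seed, ct0 + stats::rnorm(n_frames, 0, noise_sd * max(ct0)))
  } else {
    ct0
  }
  tac(times, cp, ct)
}
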