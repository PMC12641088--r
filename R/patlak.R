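#' Construct a time-activity curve object
#'
#' Dynamic acquisition frames: plasma (`cp`) and tissue (`ct`)
#' radioactivity concentrations sampled at strictly increasing times.
#'
#' @param times frame times in seconds, strictly increasing.
#' @param cp plasma concentration per frame (>= 0).
#' @param ct tissue concentration per frame.
#' @return list of class `tac`.
#' @export
tac <- function(times, cp, ct) {
  stopifnot(length(times) == length(cp), length(cp) == length(ct),
            all(is.finite(times)), all(is.finite(cp)), all(is.finite(ct)))
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (any(cp < 0)) abort("cp must be non-negative")
  structure(list(times = times, cp = cp, ct = ct), class = "tac")
}

# cumulative trapezoidal integral, same length as x (0 at the first frame)
cumtrapz <- function(t, v) {
  n <- length(t)
  c(0, cumsum(diff(t) * (v[-1] + v[-n]) / 2))
}

#' Patlak graphical transform of a time-activity curve
#'
#' The two-compartment irreversible-uptake model is linear in
#' transformed coordinates: plotting the tissue-to-plasma ratio
#' `ct(t)/cp(t)` against the normalized integral
#' `int_0^t cp dtau / cp(t)` turns the kinetics into a straight line
#' whose slope is the influx constant K1 and intercept the initial
#' distribution volume V0. The integral uses trapezoidal quadrature;
#' the abscissa is reported in minutes (frame times are seconds).
#'
#' @param curve a `tac`.
#' @return data.frame `xs` (normalized integrated time, min), `ys`
#'   (ct/cp ratio, dimensionless), `frame` (frame index).
#' @export
patlak_transform <- function(curve) {
  stopifnot(inherits(curve, "tac"))
  zero <- which(curve$cp == 0)
  if (length(zero)) {
    abort("cp is zero at frame(s) ", paste(zero, collapse = ", "),
          "; the Patlak ratio is undefined there")
  }
  integral <- cumtrapz(curve$times, curve$cp)
  data.frame(xs = integral / curve$cp / 60,
             ys = curve$ct / curve$cp,
             frame = seq_along(curve$times))
}

#' Estimate K1 and V0 from the linear portion of a Patlak plot
#'
#' Ordinary least squares of the transformed ordinate on the
#' transformed abscissa over the fit window: the slope is K1 (1/min,
#' proportional to regional cerebral blood flow) and the intercept V0
#' (dimensionless initial distribution volume). The "linear portion" of
#' the plot is not uniquely defined for real curves; the default
#' `window = "auto"` keeps the frames whose abscissa exceeds 40% of its
#' final value, and an explicit integer frame range overrides it. The
#' chosen window is recorded in the fit.
#'
#' @param curve a `tac`.
#' @param window `"auto"` or an integer vector of frame indices
#'   (>= 3 frames).
#' @return list of class `patlak_fit`: `k1`, `v0`, `fit_window`, `r2`,
#'   `n_frames`, `window_rule`.
#' @export
patlak_fit <- function(curve, window = "auto") {
  plot_df <- patlak_transform(curve)
  if (identical(window, "auto")) {
    idx <- which(plot_df$xs > 0.4 * plot_df$xs[nrow(plot_df)])
    rule <- "auto: xs > 40% of final xs"
  } else {
    idx <- as.integer(window)
    rule <- "explicit frame range"
    if (any(idx < 1L) || any(idx > nrow(plot_df))) {
      abort("window indices outside the curve")
    }
  }
  if (length(idx) < 3L) abort("fit window must contain >= 3 frames")
  xs <- plot_df$xs[idx]
  ys <- plot_df$ys[idx]
  if (max(xs) - min(xs) < .Machine$double.eps^0.5 * max(abs(xs), 1)) {
    abort("degenerate fit window: no spread in the Patlak abscissa")
  }
  fit <- stats::lm(ys ~ xs)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((ys - mean(ys))^2)
  structure(list(
    k1 = unname(stats::coef(fit)[2]),
    v0 = unname(stats::coef(fit)[1]),
    fit_window = range(idx),
    r2 = 1 - ss_res / ss_tot,
    n_frames = length(idx),
    window_rule = rule), class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("Patlak fit: K1 = %.4f /min, V0 = %.4f (R^2 = %.4f, frames %d-%d)\n",
              x$k1, x$v0, x$r2, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' A small synthetic ROI template for territory aggregation
#'
#' The study's stereotactic template places hundreds of fixed ROIs per
#' hemisphere, which is proprietary; this synthetic stand-in keeps the
#' same structure at toy scale — a few ROIs with unequal areas per
#' territory and hemisphere — so the area-weighted aggregation path is
#' exercised realistically.
#'
#' @param rois_per_territory ROIs per (territory, hemisphere) cell
#'   (default 4).
#' @return data.frame: `roi_id`, `hemisphere`, `territory`, `area`.
#' @export
toy_roi_template <- function(rois_per_territory = 4L) {
  map <- territory_display_map()
  rows <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    data.frame(
      roi_id = paste0(map$region[i], "_roi", seq_len(rois_per_territory)),
      hemisphere = map$hemisphere[i],
      territory = map$territory[i],
      # deterministic unequal areas (arbitrary units)
      area = 1 + (seq_len(rois_per_territory) - 1) * 0.5,
      stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Aggregate ROI values into the 24 arterial territories
#'
#' Segmental CBF of a territory is the area-weighted mean of its
#' constituent ROIs, computed per hemisphere. Optionally applies global
#' count normalization: division by the area-weighted mean over all
#' ROIs.
#'
#' @param roi_values named numeric vector, names = `roi_id` of the
#'   template; every template ROI must have a value.
#' @param template a template data.frame as from [toy_roi_template()].
#' @param participant_id id attached to the output rows.
#' @param global_normalize divide by the all-ROI area-weighted mean
#'   (default FALSE).
#' @return a `cbf_table` with 24 rows for this participant.
#' @export
aggregate_territories <- function(roi_values, template,
                                  participant_id = "p1",
                                  global_normalize = FALSE) {
  stopifnot(is.numeric(roi_values), !is.null(names(roi_values)),
            all(template$area > 0))
  missing <- setdiff(template$roi_id, names(roi_values))
  if (length(missing)) {
    abort("no value for ROI(s): ", paste(missing, collapse = ", "))
  }
  v <- roi_values[template$roi_id]
  w <- template$area
  if (global_normalize) v <- v / (sum(w * v) / sum(w))
  region <- paste(template$territory, template$hemisphere, sep = "_")
  agg <- vapply(split(seq_along(v), region), function(i) {
    sum(w[i] * v[i]) / sum(w[i])
  }, 0)
  out <- data.frame(participant_id = participant_id,
                    region = names(agg),
                    cbf_ml_100g_min = as.vector(agg),
                    stringsAsFactors = FALSE)
  # canonical region order; partial templates yield partial tables
  out <- out[order(match(out$region, territory_names())), , drop = FALSE]
  rownames(out) <- NULL
  validate_cbf_table(out)
}
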