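#' Compute the standard response from non-demented participants
#'
#' The standard response score of each sentence is the mean nine-point
#' rating among the non-demented (ND) participants; the standard
#' deviation uses the sample (n - 1) convention. Sentences are returned
#' in ascending order of the mean — the canonical ordering in which the
#' sentences line up with the time their adverbs denote.
#'
#' @param responses a `response_table` restricted to (or containing) ND
#'   participants; if a `group` column is present only ND rows are used.
#' @return data.frame sorted by ascending mean with columns
#'   `sentence_id`, `mean_score`, `sd_score`, `n`, `sd_flagged`
#'   (TRUE where a single observation forced the SD to 0 by convention).
#' @export
compute_standard_response <- function(responses) {
  df <- as.data.frame(responses)
  if ("group" %in% names(df)) df <- df[df$group == "ND", , drop = FALSE]
  if (!nrow(df)) abort("no ND responses available")
  present <- sort(unique(df$sentence_id))
  absent <- setdiff(1:11, present)
  if (length(absent)) {
    abort("no ND observations for sentence(s): ", paste(absent, collapse = ", "))
  }
  agg <- lapply(split(df$score, df$sentence_id), function(s) {
    n <- length(s)
    c(mean = mean(s), sd = if (n > 1) stats::sd(s) else 0, n = n)
  })
  out <- data.frame(
    sentence_id = as.integer(names(agg)),
    mean_score = vapply(agg, `[[`, 0, "mean"),
    sd_score = vapply(agg, `[[`, 0, "sd"),
    n = vapply(agg, `[[`, 0, "n"))
  out$sd_flagged <- out$n == 1
  out <- out[order(out$mean_score, out$sentence_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the pivotal-constrained regression line
#'
#' Fits `y = k (x - 5) + 5`, a line constrained through the pivotal
#' point (5, 5) that represents the "present" anchor of the nine-point
#' scale, by least squares over the single free slope k:
#' \deqn{\hat k = \sum_i (x_i-5)(y_i-5) / \sum_i (x_i-5)^2.}
#' The determination coefficient is the fraction of response variance
#' (about the mean of y) explained by the constrained line,
#' `1 - SS_res / SS_tot`; because the line is constrained it can be
#' negative, and the clamped value `max(dc_raw, 0)` (capped at 1) is
#' what enters clustering. When all y are equal, SS_tot = 0 and the
#' determination coefficient is undefined: the slope is still returned
#' with `dc` set to NA and `dc_defined = FALSE`.
#'
#' @param x abscissa, usually the standard response scores (length >= 2,
#'   not all equal to 5).
#' @param y one participant's scores, same length as x.
#' @return list of class `pivotal_fit`: `slope`, `dc_raw`, `dc`
#'   (clamped to \[0, 1\], NA when undefined), `dc_defined`, `n_points`.
#' @examples
#' s <- standard_scores_nd()$mean_score
#' fit_pivotal(s, s)  # slope 1, dc 1
#' @export
fit_pivotal <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  dx <- x - 5
  sxx <- sum(dx^2)
  if (sxx == 0) abort("degenerate design: all x equal the pivot 5")
  slope <- sum(dx * (y - 5)) / sxx
  ss_res <- sum((y - (slope * dx + 5))^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    fit <- list(slope = slope, dc_raw = NA_real_, dc = NA_real_,
                dc_defined = FALSE, n_points = length(x))
  } else {
    dc_raw <- 1 - ss_res / ss_tot
    fit <- list(slope = slope, dc_raw = dc_raw,
                dc = min(max(dc_raw, 0), 1),
                dc_defined = TRUE, n_points = length(x))
  }
  class(fit) <- "pivotal_fit"
  fit
}

#' @export
print.pivotal_fit <- function(x, ...) {
  cat(sprintf("pivotal fit: slope %.3f, d.c. %s (n = %d)\n",
              x$slope,
              if (x$dc_defined) sprintf("%.3f", x$dc) else "undefined",
              x$n_points))
  invisible(x)
}

#' Extract per-participant (slope, d.c.) features
#'
#' Plots each participant's eleven responses against the standard
#' response scores and fits the pivotal-constrained line, yielding the
#' two-dimensional (slope, determination coefficient) feature used for
#' clustering. Participants with incomplete sentence sets, and flat
#' responders whose constant scores leave the determination coefficient
#' undefined, are excluded with a logged reason.
#'
#' @param responses a `response_table`.
#' @param standard data.frame with `sentence_id` and `mean_score`
#'   (e.g. from [compute_standard_response()] or [standard_scores_nd()]).
#' @return data.frame, one row per participant: `participant_id`,
#'   `group` (NA if absent), `slope`, `dc_raw`, `dc`, `n_points`,
#'   `included`, `excluded_reason`.
#' @export
extract_features <- function(responses, standard) {
  df <- as.data.frame(responses)
  if (!nrow(df)) abort("empty response table")
  stopifnot(all(c("sentence_id", "mean_score") %in% names(standard)))
  xmap <- stats::setNames(standard$mean_score, standard$sentence_id)
  has_group <- "group" %in% names(df)
  rows <- lapply(split(df, df$participant_id), function(p) {
    out <- data.frame(
      participant_id = p$participant_id[1],
      group = if (has_group) p$group[1] else NA_character_,
      slope = NA_real_, dc_raw = NA_real_, dc = NA_real_,
      n_points = nrow(p), included = FALSE,
      excluded_reason = NA_character_,
      stringsAsFactors = FALSE)
    if (!setequal(p$sentence_id, as.integer(names(xmap))) ||
        nrow(p) != length(xmap)) {
      out$excluded_reason <- "incomplete sentence set"
      return(out)
    }
    fit <- fit_pivotal(xmap[as.character(p$sentence_id)], p$score)
    out$slope <- fit$slope
    out$dc_raw <- fit$dc_raw
    out$dc <- fit$dc
    if (!fit$dc_defined) {
      out$excluded_reason <- "constant responses: d.c. undefined"
    } else {
      out$included <- TRUE
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  excl <- out$participant_id[!out$included]
  if (length(excl)) {
    message("excluded from clustering: ",
            paste(excl, collapse = ", "))
  }
  out
}
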