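#' Metadata for the eleven A-series task sentences
#'
#' The temporal-orientation task consists of eleven short sentences,
#' each pairing one of seven adverbs of time (last week, yesterday,
#' today, now, this week, tomorrow, next week) with a verb in past or
#' present tense. Japanese expresses future events with the present
#' tense, so the three future-adverb sentences carry present-tense
#' verbs. Participants rate each sentence on a nine-point scale:
#' 1 = far past, 5 = present, 9 = far future.
#'
#' @return a data.frame with one row per sentence: `sentence_id` (1-11),
#'   `adverb`, `tense` ("past"/"present"), and `category` — the judged
#'   temporal category ("past", "present", "future") that the adverb and
#'   tense jointly convey, used by the coarse-grading response regime of
#'   the synthetic generator.
#' @seealso [standard_scores_nd()] for the reference response scores.
#' @export
sentence_metadata <- function() {
  path <- system.file("extdata", "sentences.csv", package = "temporient",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sentences(df)
  df
}

validate_sentences <- function(df) {
  need <- c("sentence_id", "adverb", "tense", "category")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort("sentence table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!setequal(df$sentence_id, 1:11) || anyDuplicated(df$sentence_id)) {
    abort("sentence ids must cover exactly 1..11")
  }
  ok_adverb <- c("last_week", "yesterday", "today", "now", "this_week",
                 "tomorrow", "next_week")
  if (!all(df$adverb %in% ok_adverb)) {
    abort("unknown adverb: ", paste(setdiff(df$adverb, ok_adverb), collapse = ", "))
  }
  if (!all(df$tense %in% c("past", "present"))) abort("tense must be past/present")
  if (!all(df$category %in% c("past", "present", "future"))) {
    abort("category must be past/present/future")
  }
  # future adverbs take the present tense in Japanese
  fut <- df$adverb %in% c("tomorrow", "next_week")
  if (!all(df$tense[fut] == "present")) abort("future-adverb sentences must be present tense")
  invisible(df)
}

#' Reference standard-response scores of the non-demented group
#'
#' The standard response score of a sentence is the mean nine-point
#' rating among the non-demented (ND) participants; it anchors the
#' abscissa of the pivotal regression and the canonical ascending
#' sentence ordering. These are the study's reference values: the "now"
#' sentence (No. 5) is rated exactly 5 by every ND participant, making
#' (5, 5) the pivotal point of the present.
#'
#' @return a data.frame sorted by ascending mean score with columns
#'   `sentence_id`, `mean_score`, `sd_score`.
#' @export
standard_scores_nd <- function() {
  path <- system.file("extdata", "standard_response_nd.csv",
                      package = "temporient", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[order(df$mean_score, df$sentence_id), , drop = FALSE]
  rownames(df) <- NULL
  stopifnot(setequal(df$sentence_id, 1:11),
            all(df$mean_score >= 1), all(df$mean_score <= 9))
  df
}
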