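#' Read a participant-by-sentence response table
#'
#' Long-format CSV with one scored sentence per row. Required columns
#' (after schema mapping): `participant_id`, `sentence_id`, `score`;
#' recognised optional columns: `group` (ND/MCI/AD), `response_time_s`,
#' `age`, `sex`, `cdr`, `mmse`. Scores must be integers on the
#' nine-point scale (1 = far past, 5 = present, 9 = far future).
#' Participants missing some of the 11 sentences are accepted at load
#' time but flagged with a message; analysis stages decide exclusion.
#'
#' @param path path to a CSV file with a header row.
#' @param schema optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(participant_id = "subj", score = "rating")`.
#' @return a validated data.frame (class `response_table`).
#' @export
read_response_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_schema(df, schema)
  validate_response_table(df)
}

#' Validate an in-memory response table
#'
#' @param df data.frame with at least `participant_id`, `sentence_id`,
#'   `score`.
#' @return the validated table (class `response_table`); every
#'   malformed row is reported by row number, none silently dropped.
#' @export
validate_response_table <- function(df) {
  need <- c("participant_id", "sentence_id", "score")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort("response table lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$score) | df$score != round(df$score) |
                 df$score < 1 | df$score > 9)
  if (length(bad)) {
    abort("scores must be integers in [1, 9]; offending rows: ",
          paste(bad, collapse = ", "))
  }
  bad_sent <- which(!(df$sentence_id %in% 1:11))
  if (length(bad_sent)) {
    abort("sentence_id must be in 1..11; offending rows: ",
          paste(bad_sent, collapse = ", "))
  }
  dup <- duplicated(df[c("participant_id", "sentence_id")])
  if (any(dup)) {
    abort("duplicated (participant, sentence) pairs at rows: ",
          paste(which(dup), collapse = ", "))
  }
  if ("group" %in% names(df) &&
      !all(df$group %in% c("ND", "MCI", "AD"))) {
    abort("group must be one of ND, MCI, AD")
  }
  n_items <- table(df$participant_id)
  incomplete <- names(n_items)[n_items < 11L]
  if (length(incomplete)) {
    message("participants with fewer than 11 sentences (kept, flagged): ",
            paste(incomplete, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  class(df) <- c("response_table", "data.frame")
  attr(df, "incomplete_participants") <- incomplete
  df
}

#' Write a response table as CSV
#' @param df a response table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participant-by-territory cerebral blood flow table
#'
#' Long-format CSV with columns (after schema mapping)
#' `participant_id`, `region`, `cbf_ml_100g_min`. Region names must be
#' among the 24 `"{territory}_{hemisphere}"` identifiers of
#' [territory_names()]; CBF values are strictly positive
#' (ml/100 g/min).
#'
#' @inheritParams read_response_table
#' @return a validated data.frame (class `cbf_table`).
#' @export
read_cbf_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_schema(df, schema)
  validate_cbf_table(df)
}

#' Validate an in-memory CBF table
#' @param df data.frame with `participant_id`, `region`,
#'   `cbf_ml_100g_min`.
#' @return the validated table (class `cbf_table`).
#' @export
validate_cbf_table <- function(df) {
  need <- c("participant_id", "region", "cbf_ml_100g_min")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort("CBF table lacks columns: ", paste(missing, collapse = ", "))
  }
  legal <- territory_names()
  unknown <- unique(df$region[!(df$region %in% legal)])
  if (length(unknown)) {
    abort("unknown region name(s): ", paste(unknown, collapse = ", "),
          "\nlegal names are: ", paste(legal, collapse = ", "))
  }
  bad <- which(!is.finite(df$cbf_ml_100g_min) | df$cbf_ml_100g_min <= 0)
  if (length(bad)) {
    abort("CBF must be strictly positive; offending rows: ",
          paste(bad, collapse = ", "))
  }
  dup <- duplicated(df[c("participant_id", "region")])
  if (any(dup)) {
    abort("duplicated (participant, region) pairs at rows: ",
          paste(which(dup), collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  class(df) <- c("cbf_table", "data.frame")
  df
}

#' Write a CBF table as CSV
#' @inheritParams write_response_table
#' @export
write_cbf_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pivot a long CBF table to a participant x region matrix
#'
#' @param df a validated `cbf_table`.
#' @param complete require all 24 regions per participant (default TRUE).
#' @return numeric matrix, rownames participant ids, colnames the 24
#'   region identifiers in canonical order.
#' @export
cbf_matrix <- function(df, complete = TRUE) {
  regions <- territory_names()
  ids <- unique(df$participant_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(regions),
              dimnames = list(ids, regions))
  m[cbind(match(df$participant_id, ids), match(df$region, regions))] <-
    df$cbf_ml_100g_min
  if (complete && anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    abort("incomplete CBF table; missing e.g. ",
          ids[holes[1, 1]], " / ", regions[holes[1, 2]])
  }
  m
}

apply_schema <- function(df, schema) {
  if (is.null(schema)) return(df)
  stopifnot(is.character(schema), !is.null(names(schema)))
  missing <- setdiff(unname(schema), names(df))
  if (length(missing)) {
    abort("schema refers to absent column(s): ", paste(missing, collapse = ", "))
  }
  names(df)[match(schema, names(df))] <- names(schema)
  df
}
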