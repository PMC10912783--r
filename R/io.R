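# Session-file I/O: one comma-delimited dialect (header required, UTF-8),
# with row-level invariant validation on read.

session_columns <- c("subject_id", "group", "med_state", "trial_index",
                     "certain_value", "gamble_low", "gamble_high",
                     "rating_prompt", "time_limit", "dominance_class",
                     "choice", "outcome", "rating")

#' Write sessions to a delimited text file
#'
#' All sessions are stacked into one comma-delimited table (header row,
#' empty fields for missing outcome/rating).
#'
#' @param sessions An `sborg_cohort`, a list of `sborg_session`s, or one
#'   session.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "sborg_cohort")) sessions <- sessions$sessions
  if (is.data.frame(sessions)) sessions <- list(sessions)
  tab <- do.call(rbind, lapply(sessions, function(s)
    as.data.frame(s)[session_columns]))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read sessions from a delimited text file
#'
#' Parses the session dialect written by [write_sessions()] (an optional
#' `col_map` renames nonstandard headers first), validates every row
#' invariant, and splits the table into per-subject-visit sessions.
#'
#' Validated invariants, reported with 1-based data row numbers:
#' outcome present if and only if the trial was responded; rating only on
#' prompted trials; outcome equal to the certain amount on certain choices
#' and equal to one of the gamble outcomes on gamble choices;
#' `gamble_low <= gamble_high`.
#'
#' @param path Input file path.
#' @param col_map Optional named character vector mapping this package's
#'   column names to the file's actual headers, e.g.
#'   `c(subject_id = "subj")`.
#' @return List of `sborg_session` data frames (empty list for a file with
#'   only a header).
#' @export
read_sessions <- function(path, col_map = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      j <- match(col_map[[std]], names(tab))
      if (is.na(j))
        stop("col_map names absent column '", col_map[[std]], "'",
             call. = FALSE)
      names(tab)[j] <- std
    }
  }
  miss <- setdiff(session_columns, names(tab))
  if (length(miss))
    stop("session file misses columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) return(list())
  tab$rating_prompt <- as.logical(tab$rating_prompt)
  validate_session_rows(tab)
  keys <- interaction(tab$subject_id, tab$med_state, drop = TRUE)
  lapply(unname(split(tab, keys)), function(s) {
    s <- s[order(s$trial_index), , drop = FALSE]
    rownames(s) <- NULL
    class(s) <- c("sborg_session", "data.frame")
    s
  })
}

validate_session_rows <- function(tab) {
  fail <- function(rows, what) {
    if (length(rows))
      stop("session file validation: ", what, " at data row(s) ",
           paste(utils::head(rows, 5L), collapse = ", "), call. = FALSE)
  }
  fail(which(!tab$choice %in% c("certain", "gamble", "timeout")),
       "unknown choice value")
  fail(which(tab$choice == "timeout" & !is.na(tab$outcome)),
       "outcome present on timeout trial")
  fail(which(tab$choice != "timeout" & is.na(tab$outcome)),
       "outcome missing on responded trial")
  fail(which(!is.na(tab$rating) & !tab$rating_prompt),
       "rating present on unprompted trial")
  fail(which(tab$choice == "timeout" & !is.na(tab$rating)),
       "rating present on timeout trial")
  fail(which(tab$gamble_low > tab$gamble_high),
       "gamble_low exceeds gamble_high")
  fail(which(tab$choice == "certain" & tab$outcome != tab$certain_value),
       "certain-choice outcome differs from certain_value")
  fail(which(tab$choice == "gamble" &
               !(tab$outcome == tab$gamble_low |
                   tab$outcome == tab$gamble_high)),
       "gamble outcome not one of the gamble values")
  invisible(TRUE)
}

#' Write a manifest or any summary table as delimited text
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
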