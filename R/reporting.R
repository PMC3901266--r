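# Submission evaluation and contest aggregation.
#
# Correctness dispatch: Categories 1/3 compare canonical molecular formulas;
# Categories 2/4 compare InChI Key skeleton blocks. Winners of a challenge
# are the external participants attaining the minimal worst-case rank among
# original submissions; the category winner has the most challenge wins.

#' Evaluate one submission against its challenge solution
#'
#' Locates every candidate matching the solution (formula identity for
#' Categories 1/3, skeleton-block identity for 2/4; unparsable candidate
#' rows are kept in the total count, warned about, and marked non-matching),
#' computes the full tie-aware metric record, and — for structure categories
#' with a fingerprint backend configured — attaches a similarity profile of
#' the candidates sorted by descending score.
#'
#' @param submission a `submission` object.
#' @param solution the matching `solution` (see [solution_for()]).
#' @param fingerprint_backend fingerprint backend for the similarity
#'   profile, or `NULL` to skip profiling. Only used for Categories 2/4.
#' @param structure_backend chemistry backend for structure identity.
#' @return an object of class `evaluation_record`: list with `participant`,
#'   `challenge`, `category`, `kind`, `metrics` (a `rank_metrics`) and
#'   `similarity` (a `similarity_profile` or `NULL`).
#' @export
evaluate_submission <- function(submission, solution,
                                fingerprint_backend = NULL,
                                structure_backend = openbabel_backend()) {
  stopifnot(inherits(submission, "submission"),
            inherits(solution, "solution"))
  if (!identical(submission$challenge, solution$challenge)) {
    stop(sprintf("challenge mismatch: submission is for %s, solution for %s",
                 submission$challenge, solution$challenge), call. = FALSE)
  }
  cand <- submission$candidates
  if (submission$category %in% c(1L, 3L)) {
    canon <- vapply(cand$candidate, function(tx) {
      tryCatch(parse_formula(tx)$canonical, error = function(e) {
        warning(sprintf("unparsable candidate formula %s (row kept, counted as non-matching)",
                        dQuote(tx)), call. = FALSE)
        NA_character_
      })
    }, character(1))
    matched <- which(!is.na(canon) & canon == solution$formula)
  } else {
    blocks <- .skeleton_blocks(cand$candidate, structure_backend)
    matched <- which(!is.na(blocks) &
                       blocks == solution$structure$skeleton_block)
  }
  metrics <- rank_metrics(cand$score, matched)

  similarity <- NULL
  if (submission$category %in% c(2L, 4L) && !is.null(fingerprint_backend)) {
    ord <- order(-cand$score)  # submission order = sorted by score
    similarity <- similarity_profile(cand$candidate[ord],
                                     solution$structure,
                                     backend = fingerprint_backend,
                                     structure_backend = structure_backend)
  }
  structure(list(participant = submission$participant,
                 challenge = submission$challenge,
                 category = submission$category,
                 kind = submission$kind,
                 metrics = metrics,
                 similarity = similarity),
            class = "evaluation_record")
}

#' @export
print.evaluation_record <- function(x, ...) {
  cat(sprintf("<evaluation_record> %s / challenge %s / category %d (%s)\n",
              x$participant, x$challenge, x$category, x$kind))
  print(x$metrics)
  invisible(x)
}

#' Flatten evaluation records to a data frame
#'
#' One row per (participant, challenge, category, kind) with all metric
#' fields; this is the serialization consumed by [write_records()] and the
#' summary functions.
#'
#' @param records a list of `evaluation_record` objects (or a single one).
#' @return a records data frame.
#' @export
records_to_df <- function(records) {
  if (inherits(records, "evaluation_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    p <- r$metrics$partition
    data.frame(
      participant = r$participant, challenge = r$challenge,
      category = r$category, kind = r$kind,
      TC = p$TC, present = p$present,
      BC = if (p$present) p$BC else NA_real_,
      EC = if (p$present) p$EC else NA_real_,
      WC = if (p$present) p$WC else NA_real_,
      rank = as.numeric(r$metrics$worst_case_rank),
      rrp = r$metrics$rrp,
      s_correct = r$metrics$s_correct,
      wBC = r$metrics$wBC, wEC = r$metrics$wEC, wrrp = r$metrics$wrrp,
      best_ts = if (!is.null(r$similarity)) r$similarity$best_ts
                else NA_real_,
      best_index = if (!is.null(r$similarity)) r$similarity$best_index
                   else NA_integer_,
      correct_index = if (!is.null(r$similarity))
                        r$similarity$correct_index else NA_integer_,
      ts_correct = if (!is.null(r$similarity) &&
                       !is.na(r$similarity$correct_index))
        r$similarity$per_candidate_ts[r$similarity$correct_index]
        else NA_real_)
  })
  do.call(rbind, rows)
}

#' Winners of one challenge within one category
#'
#' Among the eligible participants' original submissions containing the
#' correct answer, the winners are all participants attaining the minimal
#' worst-case rank. Resubmissions never count towards winning, and internal
#' participants are excluded via `eligible`.
#'
#' @param records records data frame restricted to one (challenge, category).
#' @param eligible character vector of eligible (external) participant ids;
#'   default all participants in `records`.
#' @return character vector of winning participant ids (possibly empty).
#' @export
challenge_winners <- function(records, eligible = unique(records$participant)) {
  r <- records[records$kind == "original" &
                 records$participant %in% eligible &
                 records$present & !is.na(records$rank), , drop = FALSE]
  if (nrow(r) == 0L) return(character(0))
  sort(unique(r$participant[r$rank == min(r$rank)]))
}

#' Per-participant win counts across a category
#'
#' @param records records data frame for one category.
#' @inheritParams challenge_winners
#' @return named integer vector of win counts, one entry per eligible
#'   participant appearing in `records` (zero wins included).
#' @export
category_wins <- function(records, eligible = unique(records$participant)) {
  participants <- sort(intersect(unique(records$participant), eligible))
  wins <- setNames(integer(length(participants)), participants)
  for (ch in unique(records$challenge)) {
    w <- challenge_winners(records[records$challenge == ch, , drop = FALSE],
                           eligible)
    wins[w] <- wins[w] + 1L
  }
  wins
}

#' Category winner(s)
#'
#' The participant(s) with the most challenge wins, based on original
#' submissions from eligible participants; ties are returned as a set.
#'
#' @param wins named win-count vector from [category_wins()] (or a records
#'   data frame, in which case wins are computed first).
#' @inheritParams challenge_winners
#' @return character vector of winning participant ids.
#' @export
category_winner <- function(wins, eligible = NULL) {
  if (is.data.frame(wins)) {
    wins <- if (is.null(eligible)) category_wins(wins)
            else category_wins(wins, eligible)
  }
  if (!length(wins) || max(wins) == 0L) return(character(0))
  sort(names(wins)[wins == max(wins)])
}

# Record selection for the two table kinds: "original" uses pre-deadline
# entries only; "resubmitted-merged" uses the resubmission where one exists
# and falls back to the original otherwise.
.select_kind <- function(records, kind) {
  if (kind == "original") {
    return(records[records$kind == "original", , drop = FALSE])
  }
  key <- paste(records$participant, records$challenge, records$category)
  resub <- records$kind == "resubmission"
  keep <- resub | !(key %in% key[resub])
  records[keep, , drop = FALSE]
}

.mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x)) mean(x) else NA_real_
}

.summary_row <- function(id_col, id, r, wins) {
  pres <- r[r$present, , drop = FALSE]
  out <- data.frame(
    id = id,
    n_submissions = nrow(r),
    n_correct = sum(r$present),
    n_wins = wins,
    avg_rank = .mean_or_na(pres$rank),
    avg_TC = .mean_or_na(r$TC),             # over ALL submissions
    avg_BC = .mean_or_na(pres$BC),
    avg_RRP = .mean_or_na(pres$rrp),        # over defined-RRP records
    avg_wRRP = .mean_or_na(pres$wrrp),
    avg_s_correct = .mean_or_na(pres$s_correct))
  names(out)[1] <- id_col
  stopifnot(is.na(wins) || out$n_wins <= out$n_correct,
            out$n_correct <= out$n_submissions)
  out
}

#' Summary table by participant
#'
#' One row per participant with submission/correct/win counts and the
#' averaged metrics, reproducing the aggregation conventions of the contest
#' summary tables: `avg_rank`, `avg_BC`, `avg_wRRP` and `avg_s_correct`
#' average over records where the correct answer is present; `avg_RRP`
#' averages over records where the RRP is defined; `avg_TC` averages over
#' all submissions. Undefined averages are `NA` (rendered as a dash by
#' [format_summary()]).
#'
#' @param records records data frame for one category.
#' @param kind `"original"` or `"resubmitted-merged"` (the latter uses the
#'   resubmission where available and the original otherwise). Wins are
#'   always counted on original submissions.
#' @param eligible participants eligible to win (default: all).
#' @return a summary data frame, one row per participant.
#' @export
summarize_by_participant <- function(records,
                                     kind = c("original",
                                              "resubmitted-merged"),
                                     eligible = unique(records$participant)) {
  kind <- match.arg(kind)
  stopifnot(length(unique(records$category)) <= 1L)
  wins <- category_wins(records, eligible)
  sel <- .select_kind(records, kind)
  rows <- lapply(sort(unique(sel$participant)), function(pid) {
    .summary_row("participant", pid,
                 sel[sel$participant == pid, , drop = FALSE],
                 if (pid %in% names(wins)) wins[[pid]] else NA_integer_)
  })
  do.call(rbind, rows)
}

#' Summary table by challenge
#'
#' As [summarize_by_participant()] with the grouping transposed; win counts
#' do not apply and are reported as `NA`. The conventional table uses
#' resubmitted entries where available, hence the default `kind`.
#'
#' @inheritParams summarize_by_participant
#' @return a summary data frame, one row per challenge.
#' @export
summarize_by_challenge <- function(records,
                                   kind = c("resubmitted-merged",
                                            "original"),
                                   eligible = unique(records$participant)) {
  kind <- match.arg(kind)
  stopifnot(length(unique(records$category)) <= 1L)
  sel <- .select_kind(records, kind)
  rows <- lapply(unique(sel$challenge), function(ch) {
    .summary_row("challenge", ch, sel[sel$challenge == ch, , drop = FALSE],
                 NA_integer_)
  })
  do.call(rbind, rows)
}

#' Format a summary table for display
#'
#' Rank-scale averages are rounded to 2 decimals, unit-interval metrics to
#' 3 decimals; undefined values render as a dash. Counts render as
#' `correct(wins)` in the conventional style.
#'
#' @param summary a data frame from [summarize_by_participant()] or
#'   [summarize_by_challenge()].
#' @return a character data frame ready for TSV or aligned-text output.
#' @export
format_summary <- function(summary) {
  fmt <- function(x, digits) ifelse(is.na(x), "-",
                                    formatC(x, format = "f",
                                            digits = digits))
  out <- data.frame(summary[1], check.names = FALSE)
  out$subm <- as.character(summary$n_submissions)
  out$`cor(win)` <- ifelse(
    is.na(summary$n_wins), as.character(summary$n_correct),
    sprintf("%d(%d)", summary$n_correct, summary$n_wins))
  out$avg_rank <- fmt(summary$avg_rank, 2)
  out$avg_TC <- fmt(summary$avg_TC, 1)
  out$avg_BC <- fmt(summary$avg_BC, 1)
  out$avg_RRP <- fmt(summary$avg_RRP, 3)
  out$avg_wRRP <- fmt(summary$avg_wRRP, 3)
  out$avg_s <- fmt(summary$avg_s_correct, 3)
  out
}

#' Aligned plain-text rendering of a formatted summary table
#'
#' @param formatted output of [format_summary()].
#' @return a single string (lines joined by newlines).
#' @export
summary_text <- function(formatted) {
  m <- rbind(names(formatted), as.matrix(formatted))
  widths <- apply(nchar(m), 2, max)
  pad <- function(row) paste(mapply(function(cell, w)
    formatC(cell, width = w, flag = "-"), row, widths), collapse = "  ")
  lines <- apply(m, 1, pad)
  paste(trimws(lines, which = "right"), collapse = "\n")
}

#' Similarity plot data for structure-category records
#'
#' Emits one row per candidate of every evaluated structure submission:
#' participant, challenge, candidate position in the score-sorted list, the
#' Tanimoto similarity to the solution, and markers for the correct and the
#' most similar candidate. This is the plot-ready table behind the
#' per-challenge candidate-similarity figures (dash plots with a log-scaled
#' candidate axis).
#'
#' @param records a list of `evaluation_record` objects carrying similarity
#'   profiles.
#' @return a data frame with columns `participant`, `challenge`,
#'   `candidate_rank_position`, `ts`, `is_correct`, `is_best`.
#' @export
profile_plot_data <- function(records) {
  if (inherits(records, "evaluation_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    if (is.null(r$similarity)) return(NULL)
    s <- r$similarity
    n <- length(s$per_candidate_ts)
    data.frame(participant = r$participant, challenge = r$challenge,
               candidate_rank_position = seq_len(n),
               ts = s$per_candidate_ts,
               is_correct = seq_len(n) == (s$correct_index %||% 0L),
               is_best = seq_len(n) == (s$best_index %||% 0L))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(participant = character(0), challenge = character(0),
                      candidate_rank_position = integer(0), ts = numeric(0),
                      is_correct = logical(0), is_best = logical(0)))
  }
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x

utils::globalVariables(c("participant", "candidate_rank_position", "ts"))

#' Plot similarity profiles (optional image writer)
#'
#' Renders the dash-plot representation of [profile_plot_data()] output with
#' ggplot2: one dash per candidate whose length encodes the similarity to
#' the solution, candidates on a log-scaled axis, the correct answer circled
#' and the most similar candidate highlighted. Requires ggplot2; bit-exact
#' rendering is not a contract — the tabular data are the interface.
#'
#' @param plot_data output of [profile_plot_data()] for one challenge.
#' @return a ggplot object.
#' @export
plot_similarity_profiles <- function(plot_data) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_similarity_profiles requires the ggplot2 package",
         call. = FALSE)
  }
  ggplot2::ggplot(plot_data,
                  ggplot2::aes(x = participant,
                               y = candidate_rank_position)) +
    ggplot2::geom_point(ggplot2::aes(size = ts),
                        shape = 95, colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(data = plot_data[plot_data$is_best, , drop = FALSE],
                        colour = "blue", shape = 95, size = 6) +
    ggplot2::geom_point(data = plot_data[plot_data$is_correct, ,
                                         drop = FALSE],
                        colour = "darkgreen", shape = 1, size = 4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "candidate (log scale)", size = "TS") +
    ggplot2::theme_minimal()
}
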