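# Tie-aware ranking metrics for one scored candidate list.
#
# For every submission the candidates are partitioned, relative to the score
# of the correct candidate, into BC (strictly better score), EC (equal score,
# including the correct candidate itself) and WC (strictly worse), with
# TC = BC + EC + WC. Higher scores are always better. Score equality is exact
# floating-point equality: ties arise from identically reported scores, not
# from numerical noise, so no epsilon is applied.

#' Partition candidate scores around the correct candidate
#'
#' When several candidates match the solution (stereoisomer duplicates share
#' a skeleton block), the match with the highest score is the reference; the
#' remaining matched duplicates are counted in whichever stratum their score
#' places them. An empty `matched_indices` means the correct answer is absent
#' (`present = FALSE`) and the partition counts are undefined.
#'
#' @param scores numeric vector of candidate scores (any order).
#' @param matched_indices integer indices of candidates matching the
#'   solution; may be empty.
#' @return an object of class `score_partition`: list with `TC`, `BC`, `EC`,
#'   `WC`, `present`, and `reference_index` (index of the highest-scoring
#'   match, `NA` when absent).
#' @examples
#' partition_scores(c(5, 4, 3, 2, 1), 3L)  # BC=2, EC=1, WC=2
#' @export
partition_scores <- function(scores, matched_indices = integer(0)) {
  if (length(scores) == 0L) stop("empty submission", call. = FALSE)
  stopifnot(is.numeric(scores), !anyNA(scores))
  matched_indices <- as.integer(matched_indices)
  if (length(matched_indices) &&
      (anyNA(matched_indices) || any(matched_indices < 1L) ||
       any(matched_indices > length(scores)))) {
    stop("matched_indices out of range", call. = FALSE)
  }
  tc <- length(scores)
  if (length(matched_indices) == 0L) {
    p <- list(TC = tc, BC = NA_integer_, EC = NA_integer_, WC = NA_integer_,
              present = FALSE, reference_index = NA_integer_)
    return(structure(p, class = "score_partition"))
  }
  ref_index <- matched_indices[which.max(scores[matched_indices])]
  ref <- scores[ref_index]
  p <- list(TC = tc,
            BC = sum(scores > ref),
            EC = sum(scores == ref),
            WC = sum(scores < ref),
            present = TRUE,
            reference_index = ref_index)
  stopifnot(p$BC + p$EC + p$WC == p$TC, p$EC >= 1L)
  structure(p, class = "score_partition")
}

#' @export
print.score_partition <- function(x, ...) {
  if (x$present) {
    cat(sprintf("<score_partition> TC=%d BC=%d EC=%d WC=%d\n",
                x$TC, x$BC, x$EC, x$WC))
  } else {
    cat(sprintf("<score_partition> TC=%d (correct answer absent)\n", x$TC))
  }
  invisible(x)
}

#' Worst-case absolute rank
#'
#' `BC + EC`: the rank of the correct candidate assuming it loses every tie.
#' For a unique correct score `EC = 1` and the worst-case rank is the
#' ordinary rank.
#'
#' @param p a `score_partition`.
#' @return integer rank in `[1, TC]`, or `NA` when the correct answer is
#'   absent.
#' @export
worst_case_rank <- function(p) {
  stopifnot(inherits(p, "score_partition"))
  if (!p$present) return(NA_integer_)
  r <- as.integer(p$BC + p$EC)
  stopifnot(r >= 1L, r <= p$TC)
  r
}

#' Relative ranking position (RRP)
#'
#' `RRP = (1 + (WC - BC) / (TC - 1)) / 2`, in `[0, 1]` with 1 best. It is
#' defined only when the correct candidate is present and `TC >= 2`; when all
#' candidates share one score it equals 0.5.
#'
#' @param p a `score_partition`.
#' @return the RRP, or `NA` when undefined (undefined is a value here, not an
#'   error).
#' @export
relative_rank <- function(p) {
  stopifnot(inherits(p, "score_partition"))
  if (!p$present || p$TC < 2L) return(NA_real_)
  rrp <- 0.5 * (1 + (p$WC - p$BC) / (p$TC - 1))
  stopifnot(rrp >= 0, rrp <= 1)
  rrp
}

#' Normalize submission scores to unit sum
#'
#' Divides each score by the total so that the normalized scores sum to 1,
#' making differently calibrated scoring schemes comparable. Scores must be
#' non-negative with a positive sum; negative scores are rejected rather than
#' shifted because normalization is undefined for mixed-sign scores.
#'
#' @param scores numeric vector of raw scores.
#' @return numeric vector of the same length summing to 1 (within 1e-9).
#' @export
normalize_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty submission", call. = FALSE)
  stopifnot(is.numeric(scores), !anyNA(scores))
  if (any(scores < 0)) stop("scores must be non-negative", call. = FALSE)
  total <- sum(scores)
  if (total <= 0) stop("degenerate scores: all scores are zero", call. = FALSE)
  out <- scores / total
  stopifnot(abs(sum(out) - 1) <= 1e-9)
  out
}

#' Score-weighted relative ranking position (wRRP)
#'
#' With normalized scores, `wBC` is the score mass strictly above the correct
#' candidate's score and `wEC` the mass exactly equal to it excluding the
#' correct candidate itself; `wRRP = 1 - wBC - wEC`, in `(0, 1]`. A unique
#' top-ranked correct candidate gives `wRRP = 1`; uniform scores give
#' `wRRP = 1 / TC`.
#'
#' Note the deliberate asymmetry with the rank: `EC` includes the correct
#' candidate, `wEC` excludes it.
#'
#' @param normalized_scores output of [normalize_scores()].
#' @param p the matching `score_partition`.
#' @param matched_best_index index of the highest-scoring matched candidate
#'   (defaults to `p$reference_index`).
#' @return list with `wBC`, `wEC`, `s_correct` and `wrrp`, all `NA` when the
#'   correct answer is absent.
#' @export
weighted_rrp <- function(normalized_scores, p,
                         matched_best_index = p$reference_index) {
  stopifnot(inherits(p, "score_partition"))
  if (!p$present) {
    return(list(wBC = NA_real_, wEC = NA_real_, s_correct = NA_real_,
                wrrp = NA_real_))
  }
  stopifnot(length(normalized_scores) == p$TC,
            matched_best_index >= 1L, matched_best_index <= p$TC)
  s_correct <- normalized_scores[matched_best_index]
  wbc <- sum(normalized_scores[normalized_scores > s_correct])
  eq <- setdiff(which(normalized_scores == s_correct), matched_best_index)
  wec <- sum(normalized_scores[eq])
  wrrp <- 1 - wbc - wec
  # wrrp is in (0, 1] whenever the correct candidate's score is positive; a
  # correct candidate reported with score 0 degenerates to wrrp = 0.
  stopifnot(wbc + wec + s_correct <= 1 + 1e-9, wrrp >= 0, wrrp <= 1 + 1e-12)
  list(wBC = wbc, wEC = wec, s_correct = s_correct, wrrp = min(wrrp, 1))
}

#' Full metric record for one scored candidate list
#'
#' Convenience wrapper running [partition_scores()], [worst_case_rank()],
#' [relative_rank()], [normalize_scores()] and [weighted_rrp()] in one call.
#'
#' @inheritParams partition_scores
#' @return an object of class `rank_metrics`: list with `partition`,
#'   `worst_case_rank`, `rrp`, `s_correct`, `wBC`, `wEC`, `wrrp` and
#'   `matched_best_index`.
#' @export
rank_metrics <- function(scores, matched_indices = integer(0)) {
  p <- partition_scores(scores, matched_indices)
  w <- weighted_rrp(normalize_scores(scores), p)
  structure(list(partition = p,
                 worst_case_rank = worst_case_rank(p),
                 rrp = relative_rank(p),
                 s_correct = w$s_correct,
                 wBC = w$wBC, wEC = w$wEC, wrrp = w$wrrp,
                 matched_best_index = p$reference_index),
            class = "rank_metrics")
}

#' @export
print.rank_metrics <- function(x, ...) {
  p <- x$partition
  if (p$present) {
    cat(sprintf(
      "<rank_metrics> TC=%d BC=%d EC=%d WC=%d rank=%d RRP=%s wRRP=%s s~=%s\n",
      p$TC, p$BC, p$EC, p$WC, x$worst_case_rank,
      ifelse(is.na(x$rrp), "undef.", sprintf("%.3f", x$rrp)),
      sprintf("%.3f", x$wrrp), sprintf("%.3f", x$s_correct)))
  } else {
    cat(sprintf("<rank_metrics> TC=%d, correct answer absent\n", p$TC))
  }
  invisible(x)
}
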