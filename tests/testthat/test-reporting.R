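test_that("evaluation dispatches on category: formulas vs skeleton blocks", {
  sol <- make_solution("ethanol")
  # Category 1: formula identity, third-best unique score
  sub <- new_submission("A", 1L, "1", "original",
                        candidate = c("C3H8", "C2H4O2", "C2H6O", "CH4O",
                                      "C4H10"),
                        score = c(9, 7, 5, 3, 1))
  rec <- evaluate_submission(sub, sol)
  expect_identical(rec$metrics$worst_case_rank, 3L)
  expect_null(rec$similarity)

  # Category 2: skeleton identity; single correct candidate, TC = 1
  sub2 <- new_submission("A", 2L, "1", "original", candidate = "OCC",
                         score = 1)
  rec2 <- evaluate_submission(sub2, sol, structure_backend = ob)
  expect_identical(rec2$metrics$partition$TC, 1L)
  expect_identical(rec2$metrics$worst_case_rank, 1L)
  expect_identical(rec2$metrics$rrp, NA_real_)  # undefined at TC = 1

  # challenge mismatch is an error
  expect_error(
    evaluate_submission(new_submission("A", 1L, "9", "original", "CH4", 1),
                        sol),
    "mismatch")
})

test_that("absent correct answer still yields a similarity profile", {
  sol <- make_solution("caffeine")
  sub <- new_submission("A", 2L, "1", "original",
                        candidate = c("Cn1cnc2c1c(=O)[nH]c(=O)n2C", "CCO"),
                        score = c(2, 1))  # theobromine, ethanol
  rec <- evaluate_submission(sub, sol, fingerprint_backend = fp2,
                             structure_backend = ob)
  expect_false(rec$metrics$partition$present)
  expect_identical(rec$metrics$worst_case_rank, NA_integer_)
  expect_s3_class(rec$similarity, "similarity_profile")
  expect_identical(rec$similarity$correct_index, NA_integer_)
  expect_identical(rec$similarity$best_index, 1L)  # theobromine closest
})

test_that("unparsable candidate rows stay in TC but cannot match", {
  sol <- make_solution("ethanol")
  sub <- new_submission("A", 2L, "1", "original",
                        candidate = c("CCO", "zz((", "CCC"),
                        score = c(3, 2, 1))
  expect_warning(rec <- evaluate_submission(sub, sol, structure_backend = ob),
                 "unparsable")
  expect_identical(rec$metrics$partition$TC, 3L)
  expect_identical(rec$metrics$worst_case_rank, 1L)
})

test_that("challenge winners take the best worst-case rank among originals", {
  df <- records_fixture(list(
    list(participant = "A", challenge = "1", scores = c(2, 1), matched = 1L),
    list(participant = "B", challenge = "1", scores = c(2, 1), matched = 1L),
    list(participant = "C", challenge = "1",
         scores = c(rep(3, 44), 2, rep(1, 100)), matched = 45L)))
  expect_identical(challenge_winners(df), c("A", "B"))
  # eligibility excludes internal participants
  expect_identical(challenge_winners(df, eligible = c("B", "C")), "B")

  # {A:4, B:5} -> A alone
  df2 <- records_fixture(list(
    list(participant = "A", challenge = "5", scores = c(5:1), matched = 2L),
    list(participant = "B", challenge = "5", scores = c(5:1), matched = 1L)))
  df2$rank <- c(4, 5)  # ranks 4 and 5
  expect_identical(challenge_winners(df2), "A")

  # no correct answers: empty winner set
  df3 <- records_fixture(list(
    list(participant = "A", challenge = "1", scores = c(1, 2),
         matched = integer(0))))
  expect_identical(challenge_winners(df3), character(0))

  # resubmissions never win
  df4 <- records_fixture(list(
    list(participant = "A", challenge = "1", scores = c(2, 1), matched = 2L),
    list(participant = "B", challenge = "1", scores = c(2, 1), matched = 2L,
         kind = "resubmission")))
  expect_identical(challenge_winners(df4), "A")
})

test_that("category winners have the most wins; ties returned as sets", {
  mk <- function(participant, challenge, win) {
    list(participant = participant, challenge = challenge,
         scores = c(2, 1), matched = if (win) 1L else 2L)
  }
  df <- records_fixture(list(
    mk("A", "1", TRUE), mk("B", "1", FALSE),
    mk("A", "2", TRUE), mk("B", "2", FALSE),
    mk("A", "3", TRUE), mk("B", "3", TRUE)))
  wins <- category_wins(df)
  expect_identical(wins, c(A = 3L, B = 1L))
  expect_identical(category_winner(wins), "A")
  expect_identical(category_winner(df), "A")

  # a tie at the top returns both
  df2 <- records_fixture(list(mk("A", "1", TRUE), mk("B", "2", TRUE)))
  expect_identical(category_winner(df2), c("A", "B"))
  # nobody correct: no winner
  df3 <- records_fixture(list(list(participant = "A", challenge = "1",
                                   scores = c(2, 1),
                                   matched = integer(0))))
  expect_identical(category_winner(df3), character(0))
})

test_that("participant summaries follow the averaging conventions", {
  # nine correct records with ranks {1 x 8, 2 x 1} plus two misses:
  # avg rank printed as 1.11, averaged over correct-present records only
  cases <- c(
    lapply(1:8, function(i) list(participant = "D", challenge = as.character(i),
                                 scores = c(2, 1), matched = 1L)),
    list(list(participant = "D", challenge = "9", scores = c(2, 1),
              matched = 2L)),
    lapply(10:11, function(i) list(participant = "D",
                                   challenge = as.character(i),
                                   scores = c(2, 1), matched = integer(0))))
  df <- records_fixture(cases)
  s <- summarize_by_participant(df, "original")
  expect_identical(s$n_submissions, 11L)
  expect_identical(s$n_correct, 9L)
  expect_equal(s$avg_rank, 10 / 9)
  expect_identical(format_summary(s)$avg_rank, "1.11")
  # avg_TC over all submissions, avg_BC over correct-present only
  expect_equal(s$avg_TC, 2)
  expect_equal(s$avg_BC, 1 / 9)

  # undefined averages render as a dash (every record has TC = 1)
  df2 <- records_fixture(list(
    list(participant = "O", challenge = "1", scores = 1, matched = 1L),
    list(participant = "O", challenge = "2", scores = 1, matched = 1L)))
  s2 <- summarize_by_participant(df2, "original")
  expect_identical(s2$avg_RRP, NA_real_)
  expect_identical(format_summary(s2)$avg_RRP, "-")
  expect_equal(s2$avg_wRRP, 1)  # wRRP is defined at TC = 1

  # summarize on a single record returns the record's values unchanged
  one <- records_fixture(list(list(participant = "X", challenge = "1",
                                   scores = c(3, 2, 1), matched = 2L)))
  s3 <- summarize_by_participant(one, "original")
  expect_equal(s3$avg_rank, one$rank)
  expect_equal(s3$avg_RRP, one$rrp)
  expect_equal(s3$avg_wRRP, one$wrrp)
})

test_that("resubmitted-merged selection prefers resubmissions per challenge", {
  df <- records_fixture(list(
    list(participant = "A", challenge = "1", scores = c(2, 1), matched = 2L),
    list(participant = "A", challenge = "1", scores = c(2, 1), matched = 1L,
         kind = "resubmission"),
    list(participant = "A", challenge = "2", scores = c(2, 1), matched = 1L)))
  orig <- summarize_by_participant(df, "original")
  merged <- summarize_by_participant(df, "resubmitted-merged")
  expect_identical(orig$n_submissions, 2L)
  expect_identical(merged$n_submissions, 2L)   # challenge 1 resub + 2 orig
  expect_equal(orig$avg_rank, 1.5)             # ranks 2 and 1
  expect_equal(merged$avg_rank, 1.0)           # ranks 1 and 1
  # wins always counted on originals
  expect_identical(merged$n_wins, orig$n_wins)
})

test_that("challenge summaries transpose the grouping", {
  df <- records_fixture(list(
    list(participant = "A", challenge = "c1", scores = c(2, 1), matched = 1L),
    list(participant = "B", challenge = "c1", scores = c(3, 1), matched = 1L),
    list(participant = "A", challenge = "c2", scores = c(2, 1),
         matched = integer(0))))
  s <- summarize_by_challenge(df)
  expect_identical(s$challenge, c("c1", "c2"))
  expect_equal(s$avg_rank, c(1, NA))
  expect_identical(s$n_correct, c(2L, 0L))
  expect_identical(summarize_by_challenge(df[0, , drop = FALSE])$challenge,
                   NULL)  # empty record set -> empty table
})

test_that("aggregated wins equal per-challenge winner sums", {
  dir <- tempfile()
  generate_contest(dir, n_participants = 3, n_challenges = 4,
                   categories = 1L, seed = 21)
  contest <- read_contest(dir, backend = ob)
  recs <- lapply(contest$submissions, function(sub)
    evaluate_submission(sub, solution_for(contest$solutions, sub$challenge)))
  df <- records_to_df(recs)
  eligible <- contest$config$name[contest$config$external]
  wins <- category_wins(df, eligible)
  manual <- setNames(integer(length(wins)), names(wins))
  for (ch in unique(df$challenge)) {
    w <- challenge_winners(df[df$challenge == ch, ], eligible)
    manual[w] <- manual[w] + 1L
  }
  expect_identical(wins, manual)
  s <- summarize_by_participant(df, "original", eligible = eligible)
  expect_identical(setNames(s$n_wins, s$participant)[names(wins)], wins)
})

test_that("averages re-aggregate from serialized records", {
  dir <- tempfile()
  generate_contest(dir, n_participants = 2, n_challenges = 3,
                   categories = 1L, seed = 9)
  contest <- read_contest(dir, backend = ob)
  recs <- lapply(contest$submissions, function(sub)
    evaluate_submission(sub, solution_for(contest$solutions, sub$challenge)))
  df <- records_to_df(recs)
  p <- tempfile(); write_records(df, p); back <- read_records(p)
  s <- summarize_by_participant(back, "original")
  for (i in seq_len(nrow(s))) {
    r <- back[back$participant == s$participant[i], ]
    expect_equal(s$avg_rank[i], mean(r$rank[r$present]))
    expect_equal(s$avg_TC[i], mean(r$TC))
    expect_equal(s$avg_wRRP[i], mean(r$wrrp[r$present]))
  }
})

test_that("plot data marks correct and best candidates per position", {
  sol <- make_solution("ethanol")
  sub <- new_submission("A", 2L, "1", "original",
                        candidate = c("CCC", "CCO", "CCCC"),
                        score = c(3, 2, 1))
  rec <- evaluate_submission(sub, sol, fingerprint_backend = fp2,
                             structure_backend = ob)
  pd <- profile_plot_data(list(rec))
  expect_identical(nrow(pd), 3L)
  expect_identical(pd$candidate_rank_position, 1:3)
  expect_identical(which(pd$is_correct), 2L)
  expect_identical(which(pd$is_best), 2L)
  # records without profiles produce an empty, well-formed table
  rec2 <- evaluate_submission(sub, sol, structure_backend = ob)
  expect_identical(nrow(profile_plot_data(list(rec2))), 0L)
})
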