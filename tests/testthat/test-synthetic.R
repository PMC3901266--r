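test_that("bundled structures are valid with distinct skeleton blocks", {
  s <- bundled_structures()
  expect_gte(nrow(s), 50L)
  expect_false(anyDuplicated(s$skeleton_block) > 0)
  expect_true(all(c("1-aminoanthraquinone", "2-aminoanthraquinone") %in%
                    s$name))
  # spot-check a few entries against the chemistry backend
  for (i in c(1L, nrow(s) %/% 2L, nrow(s))) {
    rec <- to_structure_record(s$smiles[i], ob)
    expect_identical(rec$skeleton_block, s$skeleton_block[i])
    expect_true(formulas_equal(idrank:::.structure_formula(s$smiles[i], ob),
                               s$formula[i]))
  }
  # stereo variants share the skeleton with distinct full keys
  has_stereo <- which(nzchar(s$stereo_smiles))
  expect_gte(length(has_stereo), 3L)
  i <- has_stereo[1]
  variants <- strsplit(s$stereo_smiles[i], ";")[[1]]
  keys <- vapply(variants, function(v) to_structure_record(v, ob)$inchikey,
                 character(1))
  expect_identical(unique(substr(keys, 1, 14)), s$skeleton_block[i])
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("generated submissions realise the requested partition exactly", {
  sol <- make_solution("caffeine")
  spec <- submission_spec(TC = 6L, BC = 4L, EC = 1L, seed = 7L)
  sub <- generate_submission(spec, sol, category = 1L)
  m <- evaluate_submission(sub, sol)$metrics
  expect_identical(m$worst_case_rank, 5L)
  expect_equal(m$rrp, 0.20)

  spec <- submission_spec(TC = 1423L, BC = 21L, EC = 24L, force_ties = TRUE,
                          seed = 8L)
  sub <- generate_submission(spec, sol, category = 1L)
  m <- evaluate_submission(sub, sol)$metrics
  expect_identical(m$partition$WC, 1378L)
  expect_identical(m$worst_case_rank, 45L)
  expect_equal(round(m$rrp, 2), 0.98)
})

test_that("infeasible specs are rejected up front", {
  expect_error(submission_spec(TC = 5L, BC = 3L, EC = 3L), "BC \\+ EC <= TC")
  expect_error(submission_spec(TC = 5L, BC = 1L, EC = 2L),
               "force_ties")
  expect_error(submission_spec(TC = 5L, BC = 1L, EC = 1L,
                               score_dist = "constant"),
               "constant")
  expect_error(submission_spec(TC = 5L, BC = 0L, EC = 1L,
                               n_stereo_duplicates = 5L),
               "stereo")
})

test_that("identical seeds give byte-identical submissions and contests", {
  sol <- make_solution("L-alanine")
  spec <- submission_spec(TC = 12L, BC = 2L, EC = 3L, force_ties = TRUE,
                          seed = 99L)
  p1 <- tempfile(); p2 <- tempfile()
  write_submission(generate_submission(spec, sol, category = 2L), p1)
  write_submission(generate_submission(spec, sol, category = 2L), p2)
  expect_identical(readLines(p1), readLines(p2))

  d1 <- tempfile(); d2 <- tempfile()
  generate_contest(d1, n_participants = 2, n_challenges = 2, seed = 31)
  generate_contest(d2, n_participants = 2, n_challenges = 2, seed = 31)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("stereoisomer duplicates share the skeleton and sit below the reference", {
  sol <- make_solution("D-glucose")
  spec <- submission_spec(TC = 10L, BC = 2L, EC = 1L,
                          n_stereo_duplicates = 2L, seed = 13L)
  sub <- generate_submission(spec, sol, category = 2L)
  blocks <- idrank:::.skeleton_blocks(sub$candidates$candidate, ob)
  matched <- which(blocks == sol$structure$skeleton_block)
  expect_identical(length(matched), 3L)  # correct + 2 duplicates
  expect_gt(length(unique(sub$candidates$candidate[matched])), 1L)
  m <- evaluate_submission(sub, sol, structure_backend = ob)$metrics
  # duplicates fall into WC, leaving the intended partition intact
  expect_identical(c(m$partition$BC, m$partition$EC, m$partition$WC),
                   c(2L, 1L, 7L))
  # a solution without bundled stereo variants refuses duplicates
  expect_error(
    generate_submission(submission_spec(TC = 5L, BC = 0L, EC = 1L,
                                        n_stereo_duplicates = 1L, seed = 1L),
                        make_solution("benzene"), category = 2L),
    "stereo variant")
})

test_that("include_correct = FALSE yields an absent-answer record", {
  sol <- make_solution("urea")
  spec <- submission_spec(TC = 8L, include_correct = FALSE, seed = 3L)
  sub <- generate_submission(spec, sol, category = 1L)
  rec <- evaluate_submission(sub, sol)
  expect_false(rec$metrics$partition$present)
  expect_identical(attr(sub, "intended_partition")$present, FALSE)
})

test_that("parameter recovery: random feasible specs round-trip exactly", {
  sol <- make_solution("ethanol")
  set.seed(404)
  n_cases <- 300
  for (i in seq_len(n_cases)) {
    tc <- sample(2:40, 1)
    bc <- sample(0:(tc - 1L), 1)
    ec <- sample(1:(tc - bc), 1)
    dist <- sample(c("uniform", "exponential"), 1)
    spec <- submission_spec(TC = tc, BC = bc, EC = ec, score_dist = dist,
                            force_ties = ec > 1L, seed = 10000L + i)
    sub <- generate_submission(spec, sol, category = 1L)
    m <- evaluate_submission(sub, sol)$metrics
    p <- m$partition
    expect_identical(c(p$BC, p$EC, p$WC),
                     as.integer(c(bc, ec, tc - bc - ec)))
    expect_identical(m$worst_case_rank, as.integer(bc + ec))
    expect_equal(m$rrp, 0.5 * (1 + ((tc - bc - ec) - bc) / (tc - 1)))
  }
})

test_that("contest manifests record every intended partition", {
  dir <- tempfile()
  generate_contest(dir, n_participants = 3, n_challenges = 3,
                   categories = 1L, seed = 77)
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         colClasses = "character")
  expect_identical(nrow(manifest), 9L)
  sols <- read_solutions(file.path(dir, "solutions.tsv"), backend = ob,
                         validate_formula = FALSE)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    sub <- read_submission(
      file.path(dir, "submissions", row$file), row$participant,
      as.integer(row$category), row$challenge, "original")
    p <- evaluate_submission(sub, solution_for(sols, row$challenge))$metrics$partition
    expect_identical(p$TC, as.integer(row$TC))
    expect_identical(p$present, as.logical(row$present))
    if (p$present) {
      expect_identical(c(p$BC, p$EC, p$WC),
                       as.integer(c(row$BC, row$EC, row$WC)))
    }
  }
})
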