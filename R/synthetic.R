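# Synthetic contests with known ground truth.
#
# Every submission is generated to realise an exact target partition
# (TC, BC, EC, WC), so the evaluator can be checked against the generator's
# intent on every path: formula and structure categories, ties, stereoisomer
# duplicates, absent correct answers, winner logic and the summary tables.
# Ties are always constructed by explicit score duplication, never left to
# distribution coincidence.

#' Bundled structure list
#'
#' About 55 valid SMILES (common metabolites and small aromatics, including
#' the 1-/2-aminoanthraquinone positional-isomer pair) with precomputed
#' neutral formulas and InChI Key skeleton blocks, shipped with the package
#' so that synthetic structure challenges need no external database. The
#' `stereo_smiles` column lists stereoisomer SMILES (same skeleton block,
#' distinct stereo descriptors) for a handful of entries, used to emulate
#' stereoisomer-duplicate submissions.
#'
#' @return a data frame with columns `name`, `smiles`, `formula`,
#'   `skeleton_block`, `stereo_smiles`.
#' @export
bundled_structures <- function() {
  path <- system.file("extdata", "structures.tsv", package = "idrank",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", colClasses = "character", quote = "")
}

#' Specification of one synthetic submission
#'
#' Describes the candidate list to generate: the target partition
#' `(TC, BC, EC, WC = TC - BC - EC)` relative to the correct candidate, the
#' score distribution, the number of stereoisomer duplicates of the correct
#' structure to include, and whether the correct answer is present at all.
#'
#' @param TC total candidate count (>= 1).
#' @param BC number of candidates scoring strictly better than the correct
#'   candidate.
#' @param EC number of candidates sharing the correct candidate's score,
#'   including the correct candidate itself (>= 1 when present).
#' @param include_correct is the correct answer present?
#' @param score_dist score distribution: `"uniform"` (distinct Uniform(0,1)
#'   draws), `"exponential"` (distinct Exp(rate) draws, emulating heavily
#'   skewed scoring schemes), or `"constant"` (all scores equal — forces
#'   `BC = 0`, `EC = TC`).
#' @param rate rate of the exponential distribution.
#' @param n_stereo_duplicates number of extra candidates that are
#'   stereoisomers of the correct structure (Categories 2/4 only; they are
#'   placed strictly below the correct candidate's score, i.e. inside WC).
#' @param force_ties must be `TRUE` to allow `EC > 1` under a continuous
#'   score distribution; ties are then constructed by duplicating the
#'   correct candidate's score.
#' @param seed integer seed making the generated submission reproducible.
#' @return an object of class `submission_spec`.
#' @export
submission_spec <- function(TC, BC = 0L, EC = 1L, include_correct = TRUE,
                            score_dist = c("uniform", "exponential",
                                           "constant"),
                            rate = 1, n_stereo_duplicates = 0L,
                            force_ties = FALSE, seed = 1L) {
  score_dist <- match.arg(score_dist)
  TC <- as.integer(TC); BC <- as.integer(BC); EC <- as.integer(EC)
  stopifnot(TC >= 1L, BC >= 0L, EC >= 0L, n_stereo_duplicates >= 0L)
  if (include_correct) {
    stopifnot(EC >= 1L, BC + EC <= TC)
    if (score_dist == "constant" && !(BC == 0L && EC == TC)) {
      stop("constant scores imply BC = 0 and EC = TC", call. = FALSE)
    }
    if (EC > 1L && score_dist != "constant" && !force_ties) {
      stop(paste("EC > 1 with a continuous score distribution requires",
                 "explicit tie construction; set force_ties = TRUE"),
           call. = FALSE)
    }
    wc <- TC - BC - EC
    if (n_stereo_duplicates > wc) {
      stop("n_stereo_duplicates must fit into the worse-scoring stratum",
           call. = FALSE)
    }
  }
  structure(list(TC = TC, BC = BC, EC = EC,
                 include_correct = isTRUE(include_correct),
                 score_dist = score_dist, rate = rate,
                 n_stereo_duplicates = as.integer(n_stereo_duplicates),
                 force_ties = isTRUE(force_ties),
                 seed = as.integer(seed)),
            class = "submission_spec")
}

# Distinct descending scores from the spec's distribution.
.draw_scores <- function(spec) {
  n <- spec$TC
  if (spec$score_dist == "constant") return(rep(1, n))
  draw <- function(m) switch(spec$score_dist,
                             uniform = stats::runif(m),
                             exponential = stats::rexp(m, spec$rate))
  s <- unique(draw(n))
  while (length(s) < n) s <- unique(c(s, draw(n)))
  sort(s[seq_len(n)], decreasing = TRUE)
}

# Decoy formulas distinct from the solution formula: a deterministic grid of
# CxHyNzOw compositions, already in Hill order by construction. Windows of
# the grid are memoized since the generator is called once per submission.
.formula_grid_cache <- new.env(parent = emptyenv())

.decoy_formulas <- function(n, exclude) {
  out <- character(0)
  c0 <- 1L
  while (length(out) < n) {
    key <- as.character(c0)
    f <- .formula_grid_cache[[key]]
    if (is.null(f)) {
      grid <- expand.grid(C = c0:(c0 + 9L), H = 1:20, N = 0:2, O = 0:2)
      f <- paste0(
        "C", ifelse(grid$C == 1L, "", grid$C),
        "H", ifelse(grid$H == 1L, "", grid$H),
        ifelse(grid$N == 0L, "",
               paste0("N", ifelse(grid$N == 1L, "", grid$N))),
        ifelse(grid$O == 0L, "",
               paste0("O", ifelse(grid$O == 1L, "", grid$O))))
      .formula_grid_cache[[key]] <- f
    }
    out <- setdiff(unique(c(out, f)), exclude)
    c0 <- c0 + 10L
  }
  out[seq_len(n)]
}

#' Generate one synthetic submission realising a target partition
#'
#' The returned scored candidate list, when evaluated against `solution`,
#' yields exactly the spec's `(BC, EC, WC)` partition. The correct payload is
#' the solution's canonical formula (Categories 1/3) or its SMILES
#' (Categories 2/4); decoys are formulas distinct from the solution formula,
#' or structures from [bundled_structures()] with a different skeleton
#' block. Stereoisomer duplicates of the correct structure (same skeleton
#' block, distinct stereo descriptors, available only for solutions with
#' `stereo_smiles` entries) are placed at scores strictly below the correct
#' candidate's.
#'
#' @param spec a [submission_spec()].
#' @param solution a `solution` object (see [solution_for()]).
#' @param category contest category (1-4).
#' @param participant,kind identifiers stamped on the submission.
#' @param structures decoy structure pool, default [bundled_structures()].
#' @return a `submission` with attribute `"intended_partition"` (list with
#'   `TC`, `BC`, `EC`, `WC`, `present`).
#' @export
generate_submission <- function(spec, solution, category = 1L,
                                participant = "synthetic",
                                kind = "original",
                                structures = bundled_structures()) {
  stopifnot(inherits(spec, "submission_spec"), inherits(solution, "solution"))
  set.seed(spec$seed)
  scores <- .draw_scores(spec)
  n <- spec$TC
  structural <- category %in% c(2L, 4L)

  if (spec$include_correct) {
    correct_pos <- spec$BC + 1L
    if (spec$EC > 1L && spec$score_dist != "constant") {
      scores[correct_pos + seq_len(spec$EC - 1L)] <- scores[correct_pos]
    }
  }

  if (structural) {
    pool <- structures$smiles[structures$skeleton_block !=
                                solution$structure$skeleton_block]
    if (!length(pool)) stop("no decoy structures available", call. = FALSE)
    payload <- sample(pool, n, replace = TRUE)
  } else {
    payload <- sample(.decoy_formulas(n, exclude = solution$formula), n)
  }

  partition <- list(TC = n, BC = NA_integer_, EC = NA_integer_,
                    WC = NA_integer_, present = spec$include_correct)
  if (spec$include_correct) {
    correct_payload <- if (structural) solution$structure$source_text
                       else solution$formula
    payload[correct_pos] <- correct_payload
    # other positions must not accidentally equal the correct payload
    clash <- setdiff(which(payload == correct_payload), correct_pos)
    if (length(clash)) {
      repl <- if (structural) sample(setdiff(pool, correct_payload),
                                     length(clash), replace = TRUE)
              else sample(.decoy_formulas(length(clash) + n,
                                          exclude = solution$formula),
                          length(clash))
      payload[clash] <- repl
    }
    if (spec$n_stereo_duplicates > 0L) {
      if (!structural) {
        stop("stereo duplicates only apply to structure categories",
             call. = FALSE)
      }
      idx <- match(solution$structure$source_text, structures$smiles)
      variants <- if (!is.na(idx) && nzchar(structures$stereo_smiles[idx])) {
        setdiff(strsplit(structures$stereo_smiles[idx], ";")[[1]],
                solution$structure$source_text)
      } else character(0)
      if (length(variants) < spec$n_stereo_duplicates) {
        stop(sprintf(
          "solution %s has %d bundled stereo variant(s); %d requested",
          solution$challenge, length(variants), spec$n_stereo_duplicates),
          call. = FALSE)
      }
      wc_pos <- which(scores < scores[correct_pos])
      payload[wc_pos[seq_len(spec$n_stereo_duplicates)]] <-
        variants[seq_len(spec$n_stereo_duplicates)]
    }
    partition$BC <- spec$BC
    partition$EC <- spec$EC
    partition$WC <- n - spec$BC - spec$EC
  }

  sub <- new_submission(participant, category, solution$challenge, kind,
                        candidate = payload, score = scores)
  attr(sub, "intended_partition") <- partition
  sub
}

#' Generate a full synthetic contest directory
#'
#' Writes a contest tree in the canonical on-disk dialect — `solutions.tsv`
#' (challenges drawn from the bundled structure list), `config.yaml`,
#' `submissions/` — plus a `manifest.tsv` recording every submission's
#' intended partition for oracle comparison. Identical seeds produce
#' byte-identical directories.
#'
#' @param dir output directory (created; must not already contain a
#'   contest).
#' @param n_participants number of participants (named P01, P02, ...; one
#'   internal participant is included when `n_participants >= 3`).
#' @param n_challenges number of challenges (at most the bundled structure
#'   count).
#' @param categories categories to generate submissions for (subset of 1:4).
#' @param template a function `(participant_index, challenge_index)`
#'   returning a list of spec arguments for [submission_spec()] (without
#'   `seed`), or `NULL` for a default mix of partitions including absent
#'   correct answers.
#' @param seed master seed; per-submission seeds are derived from it.
#' @return the contest directory path, invisibly.
#' @export
generate_contest <- function(dir, n_participants = 4L, n_challenges = 6L,
                             categories = c(1L, 2L), template = NULL,
                             seed = 1L) {
  structures <- bundled_structures()
  stopifnot(n_challenges >= 1L, n_challenges <= nrow(structures),
            n_participants >= 1L, all(categories %in% 1:4))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "submissions"), showWarnings = FALSE)

  set.seed(seed)
  rows <- structures[sample(nrow(structures), n_challenges), , drop = FALSE]
  solutions <- data.frame(
    challenge = as.character(seq_len(n_challenges)),
    categories = paste(sort(unique(categories)), collapse = ","),
    formula = rows$formula,
    smiles_or_inchi = rows$smiles,
    name = rows$name)
  utils::write.table(solutions, file.path(dir, "solutions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  participants <- sprintf("P%02d", seq_len(n_participants))
  internal <- if (n_participants >= 3L) participants[n_participants] else
    character(0)
  writeLines(c("participants:",
               sprintf("  - name: %s\n    external: %s", participants,
                       ifelse(participants %in% internal, "false", "true"))),
             file.path(dir, "config.yaml"))

  if (is.null(template)) {
    template <- function(i, j) {
      pick <- (i + j) %% 4L
      if (pick == 0L) list(TC = 1L, BC = 0L, EC = 1L)
      else if (pick == 1L) list(TC = 10L + j, BC = (i + j) %% 3L, EC = 1L)
      else if (pick == 2L) list(TC = 12L, BC = 2L, EC = 3L,
                                force_ties = TRUE)
      else list(TC = 8L, include_correct = FALSE)
    }
  }

  manifest <- list()
  sol_df <- suppressWarnings(
    read_solutions(file.path(dir, "solutions.tsv"), validate_formula = FALSE))
  for (i in seq_len(n_participants)) {
    for (j in seq_len(n_challenges)) {
      for (k in categories) {
        args <- template(i, j)
        if (is.null(args)) next  # abstention: no record at all
        args$seed <- (seed + 7919L * i + 104729L * j + 1299709L * k) %%
          2147483647L
        spec <- do.call(submission_spec, args)
        sub <- generate_submission(spec, solution_for(sol_df, j),
                                   category = k,
                                   participant = participants[i],
                                   structures = structures)
        fname <- sprintf("%s_cat%d_chal%s.tsv", participants[i], k, j)
        write_submission(sub, file.path(dir, "submissions", fname))
        p <- attr(sub, "intended_partition")
        manifest[[fname]] <- data.frame(
          file = fname, participant = participants[i], category = k,
          challenge = as.character(j), TC = p$TC, BC = p$BC, EC = p$EC,
          WC = p$WC, present = p$present)
      }
    }
  }
  utils::write.table(do.call(rbind, manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(dir)
}
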