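# Contest input/output.
#
# Canonical on-disk dialect: tab-separated UTF-8 with a header row.
#   solutions.tsv   challenge  categories  formula  smiles_or_inchi  name
#   submissions/<participant>_cat<k>_chal<id>[_resub].tsv
#                   candidate  score  [name]
#   config.yaml     participants: list of {name, external}
# Challenge ids are opaque strings; numbering gaps are legal.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "", fileEncoding = "UTF-8")
}

.io_fail <- function(path, line, msg) {
  stop(sprintf("%s, line %d: %s", path, line, msg), call. = FALSE)
}

#' Read and validate a challenge solutions table
#'
#' Expects a TSV with columns `challenge`, `categories` (comma-separated
#' category numbers), `formula`, `smiles_or_inchi`, `name`. Each row's
#' formula is canonicalized and the structure converted to its InChI Key;
#' the neutral formula implied by the structure must equal the declared
#' formula (a mismatch is a hard error naming the challenge).
#'
#' @param path path to the solutions TSV.
#' @param backend chemistry backend for structure validation.
#' @param validate_formula cross-validate declared formula against the
#'   structure's InChI formula layer (default `TRUE`).
#' @return a data frame of class `idrank_solutions` with one row per
#'   challenge: `challenge`, `categories`, `formula`, `smiles_or_inchi`,
#'   `name`, `inchikey`, `skeleton_block`.
#' @export
read_solutions <- function(path, backend = openbabel_backend(),
                           validate_formula = TRUE) {
  df <- .read_tsv(path)
  required <- c("challenge", "categories", "formula", "smiles_or_inchi",
                "name")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("%s: no solutions", path), call. = FALSE)
  if (anyDuplicated(df$challenge)) {
    stop(sprintf("%s: duplicated challenge id(s): %s", path,
                 paste(unique(df$challenge[duplicated(df$challenge)]),
                       collapse = ", ")), call. = FALSE)
  }
  df$formula_canonical <- NA_character_
  df$inchikey <- NA_character_
  df$skeleton_block <- NA_character_
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header occupies line 1
    f <- tryCatch(parse_formula(df$formula[i]), error = function(e)
      .io_fail(path, line, conditionMessage(e)))
    rec <- tryCatch(to_structure_record(df$smiles_or_inchi[i], backend),
                    idrank_structure_error = function(e)
                      .io_fail(path, line, conditionMessage(e)))
    if (validate_formula) {
      sf <- .structure_formula(df$smiles_or_inchi[i], backend)
      if (is.na(sf) || !formulas_equal(sf, f)) {
        stop(sprintf(
          "challenge %s: declared formula %s does not match the structure's formula %s",
          df$challenge[i], f$canonical, sf), call. = FALSE)
      }
    }
    df$formula_canonical[i] <- f$canonical
    df$inchikey[i] <- rec$inchikey
    df$skeleton_block[i] <- substr(rec$inchikey, 1, 14)
  }
  class(df) <- c("idrank_solutions", "data.frame")
  df
}

#' Extract one challenge's solution from a solutions table
#'
#' @param solutions an `idrank_solutions` data frame.
#' @param challenge challenge id.
#' @return a list of class `solution` with `challenge`, `categories`
#'   (integer vector), `formula` (canonical string), `structure`
#'   (a `structure_record`), `name`.
#' @export
solution_for <- function(solutions, challenge) {
  i <- match(as.character(challenge), solutions$challenge)
  if (is.na(i)) stop(sprintf("no solution for challenge %s", challenge),
                     call. = FALSE)
  structure(list(
    challenge = solutions$challenge[i],
    categories = as.integer(strsplit(solutions$categories[i],
                                     "[,;] *")[[1]]),
    formula = solutions$formula_canonical[i],
    structure = structure(list(source_text = solutions$smiles_or_inchi[i],
                               inchikey = solutions$inchikey[i],
                               skeleton_block = solutions$skeleton_block[i]),
                          class = "structure_record"),
    name = solutions$name[i]), class = "solution")
}

#' Read one participant submission
#'
#' Expects a TSV with columns `candidate`, `score` (and optionally `name`).
#' Rows are preserved in file order; duplicate payloads are allowed
#' (participants submitted stereoisomer duplicates). Scores must be
#' non-negative numbers. A file with a `rank` column instead of `score` is
#' converted on ingest to descending pseudo-scores `TC, TC-1, ...` with a
#' message — note that rank-only submissions cannot represent ties.
#'
#' @param path path to the submission TSV.
#' @param participant participant id.
#' @param category contest category (1-4).
#' @param challenge challenge id.
#' @param kind `"original"` or `"resubmission"`.
#' @return a list of class `submission` with `participant`, `category`,
#'   `challenge`, `kind` and `candidates` (data frame `candidate`, `score`,
#'   `name`).
#' @export
read_submission <- function(path, participant, category, challenge,
                            kind = c("original", "resubmission")) {
  kind <- match.arg(kind)
  df <- .read_tsv(path)
  if (nrow(df) == 0L) stop(sprintf("%s: empty submission", path),
                           call. = FALSE)
  if (!"candidate" %in% names(df)) {
    stop(sprintf("%s: missing column 'candidate'", path), call. = FALSE)
  }
  if (!"score" %in% names(df) && "rank" %in% names(df)) {
    r <- suppressWarnings(as.numeric(df$rank))
    if (anyNA(r)) .io_fail(path, which(is.na(r))[1] + 1L,
                           "non-numeric rank")
    message(sprintf(
      "%s: rank-only submission converted to pseudo-scores %d..1 (ties are not representable)",
      path, nrow(df)))
    df$score <- as.character(nrow(df) + 1 - r)
  }
  if (!"score" %in% names(df)) {
    stop(sprintf("%s: missing column 'score'", path), call. = FALSE)
  }
  scores <- suppressWarnings(as.numeric(df$score))
  if (anyNA(scores)) {
    .io_fail(path, which(is.na(scores))[1] + 1L,
             sprintf("non-numeric score %s",
                     dQuote(df$score[which(is.na(scores))[1]])))
  }
  if (any(scores < 0)) {
    .io_fail(path, which(scores < 0)[1] + 1L, "negative score")
  }
  new_submission(participant, category, challenge, kind,
                 candidate = df$candidate, score = scores,
                 name = if ("name" %in% names(df)) df$name else
                   NA_character_)
}

#' Construct a submission object in memory
#'
#' @inheritParams read_submission
#' @param candidate character vector of candidate payloads (formula strings
#'   for Categories 1/3, SMILES/InChI for 2/4).
#' @param score numeric vector of non-negative scores.
#' @param name optional candidate names.
#' @return a `submission` object.
#' @export
new_submission <- function(participant, category, challenge, kind,
                           candidate, score, name = NA_character_) {
  stopifnot(length(candidate) == length(score), length(candidate) >= 1L,
            all(score >= 0), category %in% 1:4,
            kind %in% c("original", "resubmission"))
  structure(list(participant = as.character(participant),
                 category = as.integer(category),
                 challenge = as.character(challenge),
                 kind = kind,
                 candidates = data.frame(candidate = as.character(candidate),
                                         score = as.numeric(score),
                                         name = rep_len(as.character(name),
                                                        length(candidate)))),
            class = "submission")
}

#' @export
print.submission <- function(x, ...) {
  cat(sprintf("<submission> %s, category %d, challenge %s (%s): %d candidates\n",
              x$participant, x$category, x$challenge, x$kind,
              nrow(x$candidates)))
  invisible(x)
}

#' Write a submission to the canonical TSV dialect
#'
#' @param submission a `submission` object.
#' @param path output path.
#' @export
write_submission <- function(submission, path) {
  df <- submission$candidates
  df$score <- sprintf("%.17g", df$score)
  if (all(is.na(df$name))) df$name <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a contest configuration file
#'
#' A YAML file with a `participants` list, each entry a mapping with `name`
#' and an `external` flag (internal participants are evaluated but ineligible
#' to win).
#'
#' @param path path to config.yaml.
#' @return data frame with columns `name`, `external`.
#' @export
read_contest_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$participants) || !length(cfg$participants)) {
    stop(sprintf("%s: no participants listed", path), call. = FALSE)
  }
  data.frame(
    name = vapply(cfg$participants, function(p) as.character(p$name), ""),
    external = vapply(cfg$participants, function(p) isTRUE(p$external),
                      logical(1)))
}

# Submission file name pattern: <participant>_cat<k>_chal<id>[_resub].tsv
.SUBMISSION_PATTERN <- "^(.+)_cat([1-4])_chal(.+?)(_resub)?\\.tsv$"

#' Read a whole contest directory
#'
#' Expects `solutions.tsv`, `config.yaml` and a `submissions/` directory of
#' per-(participant, category, challenge) TSV files named
#' `<participant>_cat<k>_chal<id>[_resub].tsv`.
#'
#' @param dir contest directory.
#' @param backend chemistry backend for solution validation.
#' @return a list of class `contest` with `solutions`, `config`,
#'   `submissions` (list of `submission` objects) and `dir`.
#' @export
read_contest <- function(dir, backend = openbabel_backend()) {
  if (!dir.exists(dir)) stop(sprintf("not a directory: %s", dir),
                             call. = FALSE)
  sol_path <- file.path(dir, "solutions.tsv")
  if (!file.exists(sol_path)) {
    stop(sprintf("missing solutions file: %s", sol_path), call. = FALSE)
  }
  solutions <- read_solutions(sol_path, backend)
  config <- read_contest_config(file.path(dir, "config.yaml"))
  sub_dir <- file.path(dir, "submissions")
  files <- if (dir.exists(sub_dir)) {
    list.files(sub_dir, pattern = "\\.tsv$")
  } else character(0)
  subs <- list()
  for (f in files) {
    m <- regmatches(f, regexec(.SUBMISSION_PATTERN, f))[[1]]
    if (length(m) == 0L) {
      warning(sprintf("ignoring file with unrecognised name: %s", f),
              call. = FALSE)
      next
    }
    subs[[f]] <- read_submission(
      file.path(sub_dir, f), participant = m[2],
      category = as.integer(m[3]), challenge = m[4],
      kind = if (nzchar(m[5])) "resubmission" else "original")
  }
  structure(list(solutions = solutions, config = config,
                 submissions = subs, dir = dir), class = "contest")
}

# Numeric columns serialized with full precision so that TSV round-trips
# reproduce every metric bit for bit.
.RECORD_NUMERIC <- c("TC", "BC", "EC", "WC", "rank", "rrp", "s_correct",
                     "wBC", "wEC", "wrrp", "best_ts", "ts_correct")
.RECORD_INTEGER <- c("category", "best_index", "correct_index")

#' Write evaluation records to TSV
#'
#' Numeric metric fields are written as full-precision decimal text
#' (`%.17g`) so that a read-back reproduces all values exactly.
#'
#' @param records a records data frame (see [records_to_df()]).
#' @param path output path.
#' @export
write_records <- function(records, path) {
  df <- as.data.frame(records)
  for (col in intersect(.RECORD_NUMERIC, names(df))) {
    df[[col]] <- ifelse(is.na(df[[col]]), "NA", sprintf("%.17g", df[[col]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read evaluation records written by [write_records()]
#'
#' @param path path to the records TSV.
#' @return a records data frame.
#' @export
read_records <- function(path) {
  df <- .read_tsv(path)
  for (col in intersect(.RECORD_NUMERIC, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in intersect(.RECORD_INTEGER, names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if ("present" %in% names(df)) df$present <- as.logical(df$present)
  df
}
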