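# Shared fixtures. The chemistry backend is memoized, so one instance is
# shared across the whole suite to avoid repeated conversions.

ob <- openbabel_backend()
cdk_fp <- cdk_fingerprint_backend(backend = ob)
fp2 <- fp2_backend()

# A solution object for a bundled structure, without touching disk.
make_solution <- function(name, challenge = "1", categories = 1:4) {
  s <- bundled_structures()
  i <- match(name, s$name)
  stopifnot(!is.na(i))
  structure(list(
    challenge = as.character(challenge),
    categories = as.integer(categories),
    formula = parse_formula(s$formula[i])$canonical,
    structure = structure(list(source_text = s$smiles[i],
                               inchikey = NA_character_,
                               skeleton_block = s$skeleton_block[i]),
                          class = "structure_record"),
    name = name), class = "solution")
}

# Write a tiny solutions TSV for the given bundled structure names.
write_solutions_fixture <- function(path, names,
                                    challenges = as.character(seq_along(names))) {
  s <- bundled_structures()
  idx <- match(names, s$name)
  stopifnot(!anyNA(idx))
  df <- data.frame(challenge = challenges, categories = "1,2",
                   formula = s$formula[idx], smiles_or_inchi = s$smiles[idx],
                   name = names)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Flat records data frame from a list of (scores, matched) cases, for
# aggregation tests that do not need chemistry.
records_fixture <- function(cases) {
  recs <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    m <- rank_metrics(cs$scores, cs$matched)
    structure(list(participant = cs$participant %||% "A",
                   challenge = cs$challenge %||% as.character(i),
                   category = cs$category %||% 1L,
                   kind = cs$kind %||% "original",
                   metrics = m, similarity = NULL),
              class = "evaluation_record")
  })
  records_to_df(recs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
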