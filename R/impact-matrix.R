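#' Build an extein-impact matrix
#'
#' An impact matrix holds one splicing-impact score per (flanking position,
#' residue) pair for the six extein positions around a split site
#' (N-3, N-2, N-1, C+1, C+2, C+3) and the 20 canonical residues. It is the
#' empirical substrate-preference table against which candidate split-site
#' windows are scored.
#'
#' @param scores A 20 x 6 numeric matrix with residue rownames and position
#'   colnames `c("N-3","N-2","N-1","C+1","C+2","C+3")`, or a data frame with
#'   a `residue` column plus those six columns. Missing residue rows are
#'   imputed as 0 with a warning.
#' @param family Intein family the scores refer to (e.g. `"DnaE"`).
#' @param source Free-text provenance of the measurements.
#' @return An `impact_matrix`: a tibble (`residue` + six position columns)
#'   with `family` and `source` attributes.
#' @export
impact_matrix <- function(scores, family = NA_character_, source = NA_character_) {
  if (is.matrix(scores)) {
    scores <- tibble(residue = rownames(scores), as_tibble(scores))
  }
  scores <- as_tibble(scores)
  if (!"residue" %in% names(scores)) abort("`scores` needs a `residue` column")
  missing_pos <- setdiff(IMPACT_POSITIONS, names(scores))
  extra <- setdiff(names(scores), c("residue", IMPACT_POSITIONS))
  if (length(missing_pos) > 0 || length(extra) > 0) {
    abort(sprintf(
      "impact matrix must have exactly the position columns %s (missing: %s; unexpected: %s)",
      paste(IMPACT_POSITIONS, collapse = ", "),
      paste(missing_pos, collapse = ", "), paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(scores$residue)) {
    abort(sprintf("duplicate residue row(s): %s",
                  paste(unique(scores$residue[duplicated(scores$residue)]), collapse = ", ")))
  }
  bad_res <- setdiff(scores$residue, AA_ALPHABET_20)
  if (length(bad_res) > 0) {
    abort(sprintf("unknown residue row(s): %s", paste(bad_res, collapse = ", ")))
  }
  for (p in IMPACT_POSITIONS) {
    if (!is.numeric(scores[[p]])) abort(sprintf("column '%s' is not numeric", p))
  }
  absent <- setdiff(AA_ALPHABET_20, scores$residue)
  if (length(absent) > 0) {
    warn(sprintf("residue row(s) %s missing; imputing 0 for all positions",
                 paste(absent, collapse = ", ")))
    fill <- as_tibble(setNames(as.list(rep(0, 6)), IMPACT_POSITIONS))
    scores <- dplyr::bind_rows(scores, tibble(residue = absent, fill))
  }
  scores <- dplyr::arrange(scores, match(.data$residue, AA_ALPHABET_20))
  structure(scores, family = family, source = source,
            class = c("impact_matrix", class(tibble())))
}

#' Read an extein-impact matrix from TSV
#'
#' Expects a header `residue` followed by the six position columns
#' `N-3 N-2 N-1 C+1 C+2 C+3` and up to 20 residue rows.
#'
#' @param path Path to the TSV file.
#' @inheritParams impact_matrix
#' @return An `impact_matrix` (see [impact_matrix()]).
#' @export
read_impact_matrix <- function(path, family = NA_character_, source = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  impact_matrix(tab, family = family, source = source %||% path)
}

#' Write an extein-impact matrix to TSV
#'
#' @param matrix An `impact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_impact_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "impact_matrix"))
  readr::write_tsv(as_tibble(matrix), path, progress = FALSE)
  invisible(path)
}

# internal: impact_matrix -> 20 x 6 numeric lookup matrix
impact_lookup <- function(matrix) {
  m <- as.matrix(as_tibble(matrix)[IMPACT_POSITIONS])
  rownames(m) <- as_tibble(matrix)$residue
  storage.mode(m) <- "double"
  m
}
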