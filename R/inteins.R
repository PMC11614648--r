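#' Read a split-intein registry
#'
#' A registry pairs the N- and C-half amino-acid sequences of naturally
#' split inteins. Two formats are accepted:
#' * FASTA with headers `<name>_N` / `<name>_C` (an optional `family=...`
#'   token in the description is picked up);
#' * JSON: an array of objects with fields `name`, `family`, `n_intein`,
#'   `c_intein` and optionally `allowed_c1` and `kinetics_note`.
#'
#' DnaE-family entries default to `allowed_c1 = "C"`, the catalytic
#' requirement of that family; other families default to the nucleophilic
#' set C/S/T/M.
#'
#' @param path Path to the registry file.
#' @return A tibble with columns `name`, `family`, `n_intein`, `c_intein`,
#'   `allowed_c1` (list column) and `kinetics_note`.
#' @examples
#' reg <- read_intein_registry(system.file("extdata",
#'   "dnae_registry_synthetic.fasta", package = "splitintein"))
#' reg$name
#' @export
read_intein_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    entries <- jsonlite::read_json(path, simplifyVector = FALSE)
    reg <- purrr::map_dfr(entries, function(e) {
      tibble(name = e$name, family = e$family %||% NA_character_,
             n_intein = toupper(e$n_intein), c_intein = toupper(e$c_intein),
             allowed_c1 = list(toupper(unlist(e$allowed_c1 %||% character(0)))),
             kinetics_note = e$kinetics_note %||% NA_character_)
    })
  } else {
    fa <- read_fasta(path, type = "protein")
    half <- dplyr::case_when(grepl("_N$", fa$id) ~ "n_intein",
                             grepl("_C$", fa$id) ~ "c_intein",
                             TRUE ~ NA_character_)
    if (any(is.na(half))) {
      abort(sprintf("registry FASTA headers must end in _N or _C; offending: %s",
                    paste(fa$id[is.na(half)], collapse = ", ")))
    }
    fa$name <- sub("_[NC]$", "", fa$id)
    fa$half <- half
    fam <- vapply(fa$desc, function(d) {
      m <- regmatches(d, regexpr("family=\\S+", d))
      if (length(m) == 0) NA_character_ else sub("^family=", "", m)
    }, character(1), USE.NAMES = FALSE)
    fa$family <- fam
    orphan <- names(which(table(fa$name) != 2))
    if (length(orphan) > 0) {
      abort(sprintf("unpaired intein half for: %s", paste(orphan, collapse = ", ")))
    }
    reg <- fa |>
      dplyr::group_by(.data$name) |>
      dplyr::summarise(
        family = dplyr::first(stats::na.omit(.data$family)) %||% NA_character_,
        n_intein = .data$seq[.data$half == "n_intein"],
        c_intein = .data$seq[.data$half == "c_intein"],
        .groups = "drop") |>
      dplyr::mutate(allowed_c1 = list(character(0)), kinetics_note = NA_character_)
  }
  reg$allowed_c1 <- purrr::map2(reg$allowed_c1, reg$family, function(a, f) {
    if (length(a) > 0) a
    else if (!is.na(f) && toupper(f) == "DNAE") "C"
    else c("C", "S", "T", "M")
  })
  if (any(!nzchar(reg$n_intein)) || any(!nzchar(reg$c_intein))) {
    abort("intein halves must be non-empty")
  }
  reg
}

#' The packaged synthetic DnaE registry
#'
#' Three DnaE-style pairs named SspDnaE / NpuDnaE / AvaDnaE with realistic
#' half lengths (N: 102-123 residues starting with Cys; C: 36 residues
#' ending in Asn). The sequences are synthetic stand-ins for bench use you
#' should replace with curated intein sequences; they exercise every design
#' step without any download.
#'
#' @return A registry tibble (see [read_intein_registry()]).
#' @export
dnae_registry <- function() {
  read_intein_registry(extdata_path("dnae_registry_synthetic.fasta"))
}
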