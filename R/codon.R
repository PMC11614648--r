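#' Read a codon usage table
#'
#' TSV with columns `residue`, `codon`, `frequency`. Relative frequencies
#' are renormalized to sum to 1 within each residue; every canonical
#' residue must have at least one codon and every codon must translate to
#' its residue under the standard genetic code.
#'
#' @param path Path to the TSV.
#' @return A tibble `residue`, `codon`, `frequency` (normalized).
#' @export
read_codon_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    residue = readr::col_character(),
    codon = readr::col_character(),
    frequency = readr::col_double()), progress = FALSE)
  tab$residue <- toupper(tab$residue)
  tab$codon <- toupper(gsub("U", "T", tab$codon))
  gc_code <- Biostrings::GENETIC_CODE
  wrong <- tab$codon[gc_code[tab$codon] != tab$residue]
  if (length(wrong) > 0 || anyNA(gc_code[tab$codon])) {
    abort(sprintf("codon(s) inconsistent with the standard genetic code: %s",
                  paste(stats::na.omit(wrong), collapse = ", ")))
  }
  missing <- setdiff(AA_ALPHABET_20, tab$residue)
  if (length(missing) > 0) {
    abort(sprintf("codon table lacks residue(s): %s", paste(missing, collapse = ", ")))
  }
  tab |>
    dplyr::group_by(.data$residue) |>
    dplyr::mutate(frequency = .data$frequency / sum(.data$frequency)) |>
    dplyr::ungroup()
}

#' The packaged human codon usage table
#'
#' Approximate human relative codon frequencies (rounded to two decimals
#' and renormalized on load; published usage tables differ slightly by
#' source and rounding).
#'
#' @return A codon table tibble (see [read_codon_table()]).
#' @export
human_codon_table <- function() {
  read_codon_table(extdata_path("human_codon_usage.tsv"))
}

#' Back-translate a protein to DNA
#'
#' Deterministic reverse translation under a codon usage table. Two modes:
#' * `"max-frequency"`: the most frequent codon per residue;
#' * `"gc-minimize"`: the lowest-GC codon among codons whose relative
#'   frequency is at least `min_freq` (default 0.10, avoiding rare codons);
#'   GC ties resolve to the more frequent codon.
#'
#' Lowering GC content eases synthesis and PCR assembly of the construct.
#' In either mode `translate_dna(back_translate(p)) == p`.
#'
#' @param protein Protein string (or data frame with `seq`).
#' @param codon_table A table from [read_codon_table()]
#'   (default [human_codon_table()]).
#' @param mode `"gc-minimize"` or `"max-frequency"`.
#' @param min_freq Frequency floor for `"gc-minimize"`.
#' @return The coding DNA sequence as a single string (no stop codon).
#' @examples
#' back_translate("MKV", mode = "max-frequency")
#' @export
back_translate <- function(protein, codon_table = human_codon_table(),
                           mode = c("gc-minimize", "max-frequency"),
                           min_freq = 0.10) {
  mode <- match.arg(mode)
  seq <- as_sequence(protein)
  check_protein_alphabet(seq)
  choice <- codon_choice(codon_table, mode, min_freq)
  residues <- strsplit(seq, "")[[1]]
  missing <- setdiff(unique(residues), names(choice))
  if (length(missing) > 0) {
    abort(sprintf("residue(s) absent from codon table: %s",
                  paste(missing, collapse = ", ")))
  }
  paste(choice[residues], collapse = "")
}

# one codon per residue for a given mode
codon_choice <- function(codon_table, mode, min_freq) {
  tab <- codon_table
  tab$gc <- gc_content(tab$codon)
  if (mode == "max-frequency") {
    picked <- tab |>
      dplyr::group_by(.data$residue) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$codon, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  } else {
    admissible <- tab[tab$frequency >= min_freq, , drop = FALSE]
    # residues whose every codon is below the floor fall back to all codons
    lost <- setdiff(unique(tab$residue), unique(admissible$residue))
    admissible <- dplyr::bind_rows(admissible, tab[tab$residue %in% lost, ])
    picked <- admissible |>
      dplyr::group_by(.data$residue) |>
      dplyr::arrange(.data$gc, dplyr::desc(.data$frequency), .data$codon,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  setNames(picked$codon, picked$residue)
}
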