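#' Translate a DNA coding sequence to protein
#'
#' Standard-genetic-code translation of an in-frame coding sequence. A stop
#' codon terminates translation; a stop before the final codon is an error
#' unless `allow_internal_stop = TRUE` (in which case translation still stops
#' there, with a warning).
#'
#' @param dna A DNA sequence string (or data frame with a `seq` column);
#'   length must be divisible by 3 and contain only A/C/G/T.
#' @param allow_internal_stop Tolerate an internal stop codon?
#' @return The translated protein as a single string.
#' @examples
#' translate_dna("ATGTAA")
#' @export
translate_dna <- function(dna, allow_internal_stop = FALSE) {
  dna <- as_sequence(dna, "dna")
  check_dna_alphabet(dna)
  if (nchar(dna) %% 3 != 0) {
    abort(sprintf("coding sequence length (%d) is not a multiple of 3", nchar(dna)))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)[[1]]
  if (stop_at > 0) {
    if (stop_at < nchar(aa)) {
      msg <- sprintf("internal stop codon at codon %d", stop_at)
      if (!allow_internal_stop) abort(msg)
      warn(msg)
    }
    aa <- substr(aa, 1, stop_at - 1)
  }
  aa
}

#' Reverse complement of a DNA sequence
#'
#' @param dna DNA string(s); vectorized.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(dna) {
  vapply(dna, function(s) {
    check_dna_alphabet(toupper(s))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of DNA sequences
#'
#' @param dna DNA string(s); vectorized.
#' @return Fraction of G+C bases in `[0, 1]`.
#' @examples
#' gc_content(c("GGCC", "ATAT", "ATGC"))
#' @export
gc_content <- function(dna) {
  vapply(dna, function(s) {
    s <- toupper(s)
    if (!nzchar(s)) abort("empty DNA sequence")
    check_dna_alphabet(s)
    chars <- strsplit(s, "")[[1]]
    sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Packaged average residue-mass table
#'
#' Average (not monoisotopic) monomer masses in daltons for the 20 canonical
#' residues, plus the mass of one water molecule; suited to gel-level size
#' comparison of expression products.
#'
#' @return A named list with `masses` (named numeric, 20 residues) and
#'   `water` (scalar, Da).
#' @export
residue_masses <- function() {
  tab <- readr::read_tsv(extdata_path("residue_masses.tsv"),
                         col_types = readr::cols(
                           residue = readr::col_character(),
                           average_mass_da = readr::col_double()
                         ), progress = FALSE)
  water <- tab$average_mass_da[tab$residue == "water"]
  masses <- setNames(tab$average_mass_da[tab$residue != "water"],
                     tab$residue[tab$residue != "water"])
  stopifnot(setequal(names(masses), AA_ALPHABET_20), all(masses > 0))
  list(masses = masses, water = water)
}

#' Molecular weight of a protein
#'
#' Sum of average residue monomer masses plus one water, in daltons.
#'
#' @param protein Protein string(s) (or a data frame with a `seq` column);
#'   vectorized over a character vector.
#' @param mass_table Optional list as returned by [residue_masses()].
#' @return Molecular weight(s) in Da.
#' @examples
#' protein_mw("G") # free glycine, 75.07 Da
#' @export
protein_mw <- function(protein, mass_table = residue_masses()) {
  if (is.data.frame(protein)) protein <- protein$seq
  vapply(protein, function(s) {
    s <- toupper(s)
    check_protein_alphabet(s)
    chars <- strsplit(s, "")[[1]]
    sum(mass_table$masses[chars]) + mass_table$water
  }, numeric(1), USE.NAMES = FALSE)
}
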