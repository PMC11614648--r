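#' Read sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file into a tibble with one row per record.
#' Sequences are uppercased and whitespace-stripped; record order is
#' preserved. The alphabet is validated against the 20 canonical amino acids
#' (`type = "protein"`) or A/C/G/T (`type = "dna"`); with `type = "auto"` the
#' type is guessed from the characters present.
#'
#' @param path Path to a FASTA file.
#' @param type One of `"auto"`, `"protein"`, `"dna"`.
#' @param strict If `TRUE` (default), characters outside the alphabet are an
#'   error; otherwise they are kept with a warning.
#' @return A tibble with columns `id` (first word of the header), `desc`
#'   (remainder of the header), `seq` and `length`.
#' @examples
#' gfp <- read_fasta(system.file("extdata", "gfp_avgfp.fasta",
#'                               package = "splitintein"))
#' gfp$length
#' @export
read_fasta <- function(path, type = c("auto", "protein", "dna"), strict = TRUE) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) abort("FASTA contains an empty sequence")
  if (type == "auto") {
    letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    type <- if (all(letters_used %in% c("A", "C", "G", "T"))) "dna" else "protein"
  }
  for (s in seqs) {
    if (type == "protein") check_protein_alphabet(s, strict = strict)
    else check_dna_alphabet(s, strict = strict)
  }
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tibble(id = unname(id), desc = unname(desc), seq = unname(seqs),
         length = unname(nchar(seqs)))
}

#' Write sequences to a FASTA file
#'
#' @param records A data frame with columns `id` and `seq` (an optional
#'   `desc` column is appended to the header).
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  header <- records$id
  if ("desc" %in% names(records)) {
    header <- ifelse(nzchar(records$desc), paste(header, records$desc), header)
  }
  lines <- purrr::map2(header, records$seq, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' The packaged GFP example protein
#'
#' Returns the 238-residue avGFP-numbered green fluorescent protein used as
#' the worked example throughout the package documentation.
#'
#' @return A one-row tibble as returned by [read_fasta()].
#' @export
gfp_protein <- function() {
  read_fasta(extdata_path("gfp_avgfp.fasta"), type = "protein")
}
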