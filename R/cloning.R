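#' Find restriction recognition sites
#'
#' Exact-match scan of the given strand for each enzyme's recognition
#' sequence. The default enzymes (BamHI, HindIII) have palindromic sites,
#' so no reverse-strand scan is needed for them.
#'
#' @param dna DNA string (or data frame with `seq`).
#' @param enzymes Named character vector of recognition sequences
#'   (default `c(BamHI = "GGATCC", HindIII = "AAGCTT")`).
#' @return A tibble `enzyme`, `site`, `start` (1-based), sorted by `start`.
#' @examples
#' find_restriction_sites("AAGCTTGGATCC")
#' @export
find_restriction_sites <- function(dna,
                                   enzymes = c(BamHI = "GGATCC", HindIII = "AAGCTT")) {
  seq <- as_sequence(dna, "dna")
  check_dna_alphabet(seq)
  if (is.null(names(enzymes)) || any(!nzchar(names(enzymes)))) {
    abort("`enzymes` must be a named vector of recognition sequences")
  }
  hits <- purrr::imap_dfr(enzymes, function(site, enz) {
    site <- toupper(site)
    starts <- gregexpr(site, seq, fixed = TRUE)[[1]]
    if (starts[1] == -1) return(tibble(enzyme = character(), site = character(),
                                       start = integer()))
    tibble(enzyme = enz, site = site, start = as.integer(starts))
  })
  dplyr::arrange(hits, .data$start, .data$enzyme)
}

#' Append restriction cloning flanks to an insert
#'
#' Adds the 5' and 3' recognition sequences (each preceded/followed by an
#' optional spacer of extra bases that many enzymes need to cut near DNA
#' ends) to a clean insert. It is an error for the insert to already
#' contain either site internally, since that would be cut during cloning.
#'
#' @param dna Insert DNA string (or data frame with `seq`).
#' @param five_prime_site,three_prime_site Recognition sequences
#'   (defaults BamHI `GGATCC` / HindIII `AAGCTT`).
#' @param spacer Extra bases outside each site (default `""`).
#' @return A tibble with `seq` (flanked sequence) and a `features` list
#'   column recording `name`, `start`, `end` for the flanks and insert.
#' @export
add_cloning_flanks <- function(dna, five_prime_site = "GGATCC",
                               three_prime_site = "AAGCTT", spacer = "") {
  seq <- as_sequence(dna, "dna")
  check_dna_alphabet(seq)
  five_prime_site <- toupper(five_prime_site)
  three_prime_site <- toupper(three_prime_site)
  internal <- find_restriction_sites(seq, c(five_prime = five_prime_site,
                                            three_prime = three_prime_site))
  if (nrow(internal) > 0) {
    abort(sprintf("insert contains restriction site(s) internally: %s",
                  paste(sprintf("%s@%d", internal$site, internal$start),
                        collapse = ", ")))
  }
  spacer <- toupper(spacer)
  out <- paste0(spacer, five_prime_site, seq, three_prime_site, spacer)
  ns <- nchar(spacer)
  n5 <- nchar(five_prime_site)
  features <- tibble(
    name = c("five_prime_flank", "insert", "three_prime_flank"),
    start = c(ns + 1, ns + n5 + 1, ns + n5 + nchar(seq) + 1),
    end = c(ns + n5, ns + n5 + nchar(seq),
            ns + n5 + nchar(seq) + nchar(three_prime_site))
  )
  tibble(seq = out, length = nchar(out), features = list(features))
}

#' Oligo melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` for oligos shorter than 14 nt; the
#' GC-fraction formula `64.9 + 41 * (GC - 16.4) / length` otherwise
#' (`GC` = number of G/C bases). These simple formulas are adequate for
#' checking overlap-extension junctions against a standard annealing
#' program; they are not nearest-neighbor estimates.
#'
#' @param oligo DNA string(s); vectorized.
#' @return Melting temperature(s) in degrees Celsius.
#' @examples
#' melting_temp("AAAAAAAAAAAA") # Wallace: 24
#' @export
melting_temp <- function(oligo) {
  vapply(oligo, function(s) {
    s <- toupper(s)
    if (!nzchar(s)) abort("empty oligo")
    check_dna_alphabet(s)
    chars <- strsplit(s, "")[[1]]
    n_gc <- sum(chars %in% c("G", "C"))
    n_at <- length(chars) - n_gc
    if (length(chars) < 14) 2 * n_at + 4 * n_gc
    else 64.9 + 41 * (n_gc - 16.4) / length(chars)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Tile a sequence into overlap-extension PCR fragments
#'
#' Splits a construct into `n_fragments` pieces for two-step
#' overlap-extension assembly: consecutive fragments share an
#' `overlap_len`-base junction (the final junction may be shorter when the
#' sequence length forces it), and each junction is reported as an oligo
#' with its melting temperature. A warning is raised when a junction melts
#' below `tm_target` (the intended annealing temperature).
#'
#' @param dna DNA string (or data frame with `seq`).
#' @param n_fragments Number of fragments (>= 1).
#' @param overlap_len Junction overlap length in bases (default 20).
#' @param tm_target Annealing temperature target in Celsius (default 60).
#' @return A list of class `primer_set` with tibbles `fragments`
#'   (`fragment`, `seq`, `start`, `end`) and `oligos` (`oligo`, `length`,
#'   `tm`, `fragment_from`, `fragment_to`).
#' @export
design_overlap_fragments <- function(dna, n_fragments, overlap_len = 20,
                                     tm_target = 60) {
  seq <- as_sequence(dna, "dna")
  check_dna_alphabet(seq)
  if (n_fragments < 1) abort("`n_fragments` must be >= 1")
  n <- nchar(seq)
  if (n_fragments == 1) {
    out <- list(fragments = tibble(fragment = 1L, seq = seq, start = 1L, end = n),
                oligos = tibble(oligo = character(), length = integer(),
                                tm = numeric(), fragment_from = integer(),
                                fragment_to = integer()),
                overlap_len = overlap_len, tm_target = tm_target)
    class(out) <- "primer_set"
    return(out)
  }
  # fragment length so that n_fragments pieces minus shared junctions cover n
  frag_len <- ceiling((n + (n_fragments - 1) * overlap_len) / n_fragments)
  step <- frag_len - overlap_len
  if (step < 1 || frag_len > n) {
    abort(sprintf(
      "sequence of %d nt is too short for %d fragments with %d nt overlaps",
      n, n_fragments, overlap_len))
  }
  starts <- 1 + (seq_len(n_fragments) - 1) * step
  ends <- pmin(starts + frag_len - 1, n)
  ends[n_fragments] <- n
  if (starts[n_fragments] > n || any(starts[-1] > ends[-n_fragments])) {
    abort(sprintf(
      "sequence of %d nt is too short for %d fragments with %d nt overlaps",
      n, n_fragments, overlap_len))
  }
  fragments <- tibble(fragment = seq_len(n_fragments),
                      seq = substring(seq, starts, ends),
                      start = as.integer(starts), end = as.integer(ends))
  junctions <- tibble(
    fragment_from = seq_len(n_fragments - 1),
    fragment_to = 2:n_fragments,
    oligo = substring(seq, starts[-1], ends[-n_fragments])
  )
  junctions$length <- nchar(junctions$oligo)
  junctions$tm <- melting_temp(junctions$oligo)
  low <- junctions$tm < tm_target
  if (any(low)) {
    warn(sprintf("junction overlap(s) melt below the %g C annealing target: %s",
                 tm_target,
                 paste(sprintf("%d-%d (%.1f C)", junctions$fragment_from[low],
                               junctions$fragment_to[low], junctions$tm[low]),
                       collapse = ", ")))
  }
  out <- list(fragments = fragments,
              oligos = junctions[, c("oligo", "length", "tm",
                                     "fragment_from", "fragment_to")],
              overlap_len = overlap_len, tm_target = tm_target)
  class(out) <- "primer_set"
  out
}

#' Reassemble overlap-extension fragments
#'
#' Merges consecutive fragments by their shared junction: the longest
#' suffix of each fragment that is a prefix of the next is merged once.
#' Reassembly of a [design_overlap_fragments()] tiling reproduces the
#' input sequence exactly.
#'
#' @param x A `primer_set` or a character vector of ordered fragments.
#' @return The merged sequence as a single string.
#' @export
merge_overlap_fragments <- function(x) {
  if (inherits(x, "primer_set")) {
    fr <- x$fragments
    # exact merge from the recorded tiling coordinates
    pieces <- c(fr$seq[[1]],
                purrr::map_chr(seq_len(nrow(fr))[-1], function(i) {
                  ov <- fr$end[i - 1] - fr$start[i] + 1
                  substr(fr$seq[i], ov + 1, nchar(fr$seq[i]))
                }))
    return(paste(pieces, collapse = ""))
  }
  frags <- as.character(x)
  if (length(frags) == 0) abort("no fragments to merge")
  out <- frags[[1]]
  for (nxt in frags[-1]) {
    max_ov <- min(nchar(out), nchar(nxt))
    ov <- 0
    for (len in rev(seq_len(max_ov))) {
      if (substr(out, nchar(out) - len + 1, nchar(out)) == substr(nxt, 1, len)) {
        ov <- len
        break
      }
    }
    if (ov == 0) warn("adjacent fragments share no overlap; concatenating")
    out <- paste0(out, substr(nxt, ov + 1, nchar(nxt)))
  }
  out
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> %d fragment(s), %d junction oligo(s), overlap %d nt\n",
              nrow(x$fragments), nrow(x$oligos), x$overlap_len))
  print(x$fragments)
  if (nrow(x$oligos) > 0) print(x$oligos)
  invisible(x)
}
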