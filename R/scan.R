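#' Enumerate candidate split positions
#'
#' A split site k divides the protein between residues k and k+1 and is
#' characterized by the six flanking residues k-2..k+3 (three on the
#' N-extein side, three on the C-extein side). Only positions with a
#' complete 6-mer window are enumerated, i.e. k in `[3, N-3]`, giving
#' N-5 sites for an N-residue protein.
#'
#' @param protein Protein sequence string or data frame with a `seq` column.
#' @return Integer vector of split positions (empty, with a warning, for
#'   proteins shorter than 6 residues).
#' @export
enumerate_split_sites <- function(protein) {
  seq <- as_sequence(protein)
  n <- nchar(seq)
  if (n < 6) {
    warn(sprintf("protein of length %d has no complete 6-residue split window", n))
    return(integer(0))
  }
  3:(n - 3)
}

#' Extract the 6-residue window around a split position
#'
#' @inheritParams enumerate_split_sites
#' @param k Split position(s); the window is residues k-2..k+3 (1-based,
#'   inclusive). Vectorized over `k`.
#' @return Character vector of 6-mers.
#' @examples
#' site_window(gfp_protein(), c(47, 69))
#' @export
site_window <- function(protein, k) {
  seq <- as_sequence(protein)
  n <- nchar(seq)
  if (any(k < 3 | k > n - 3)) {
    abort(sprintf("split position out of range [3, %d]", n - 3))
  }
  substring(seq, k - 2, k + 3)
}

#' Score a split-site window against an impact matrix
#'
#' The window score is the sum over its six positions of the matrix entry
#' for the residue observed at that position.
#'
#' @param window 6-mer window string(s); vectorized.
#' @param matrix An [impact_matrix()].
#' @param strict If `TRUE` (default) a non-canonical residue in the window
#'   is an error; otherwise it contributes 0.
#' @return Numeric score(s).
#' @export
score_window <- function(window, matrix, strict = TRUE) {
  stopifnot(inherits(matrix, "impact_matrix"))
  if (any(nchar(window) != 6)) abort("windows must be exactly 6 residues")
  lut <- impact_lookup(matrix)
  vapply(toupper(window), function(w) {
    res <- strsplit(w, "")[[1]]
    known <- res %in% rownames(lut)
    if (!all(known) && strict) {
      abort(sprintf("non-canonical residue(s) in window '%s': %s", w,
                    paste(unique(res[!known]), collapse = ", ")))
    }
    sum(lut[cbind(res[known], IMPACT_POSITIONS[known])])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a protein for ranked split sites
#'
#' Enumerates every split position with a complete 6-residue window, scores
#' each window against the extein-impact matrix, optionally annotates
#' secondary structure, and ranks sites by descending score (ties broken by
#' ascending position). The catalytic C+1 constraint is recorded
#' (`passes_c1`) but never filters or reorders the scan itself; use
#' [filter_c1()] or [select_candidates()] for that.
#'
#' @inheritParams enumerate_split_sites
#' @param matrix An [impact_matrix()].
#' @param structure Optional per-residue secondary-structure track: a
#'   character vector of H/E/C labels aligned to the protein, or anything
#'   accepted by [read_structure_track()].
#' @param allowed_c1 Residues acceptable at the C+1 position (first residue
#'   of the C-extein); default `"C"`, the DnaE-family requirement.
#' @param strict Passed to [score_window()].
#' @return A tibble of class `split_scan` with one row per site, columns
#'   `rank`, `window`, `score`, `k`, `site` (`"k/k+1"`), `c1`, `passes_c1`
#'   and (when a track is given) `structure`.
#' @examples
#' mat <- sim_impact_matrix(seed = 1, planted_window = "GVQCFS")
#' scan_split_sites(gfp_protein(), mat) |> head(3)
#' @export
scan_split_sites <- function(protein, matrix, structure = NULL,
                             allowed_c1 = "C", strict = TRUE) {
  seq <- as_sequence(protein)
  check_protein_alphabet(seq, strict = strict)
  ks <- enumerate_split_sites(seq)
  if (length(ks) == 0) {
    empty <- tibble(rank = integer(), window = character(),
                    score = numeric(), k = integer(), site = character(),
                    c1 = character(), passes_c1 = logical())
    class(empty) <- c("split_scan", class(empty))
    return(empty)
  }
  windows <- site_window(seq, ks)
  sites <- tibble(
    window = windows,
    score = score_window(windows, matrix, strict = strict),
    k = ks,
    site = sprintf("%d/%d", ks, ks + 1),
    c1 = substr(windows, 4, 4)
  )
  sites$passes_c1 <- sites$c1 %in% toupper(allowed_c1)
  if (!is.null(structure)) {
    track <- read_structure_track(structure)
    if (length(track) != nchar(seq)) {
      abort(sprintf("structure track length (%d) does not match protein length (%d)",
                    length(track), nchar(seq)))
    }
    sites$structure <- vapply(ks, function(k) majority_structure(track[(k - 2):(k + 3)]),
                              character(1))
  }
  sites <- dplyr::arrange(sites, dplyr::desc(.data$score), .data$k)
  sites <- dplyr::mutate(sites, rank = dplyr::row_number(), .before = 1)
  class(sites) <- c("split_scan", class(sites))
  sites
}

#' Keep only sites satisfying the C+1 constraint
#'
#' DnaE-family inteins require a nucleophilic residue (canonically cysteine)
#' immediately downstream of the split. Filtering keeps the original ranks
#' and never reorders surviving sites.
#'
#' @param sites A scan result from [scan_split_sites()].
#' @param allowed Allowed C+1 residues (default `"C"`).
#' @return The surviving subset of `sites`.
#' @export
filter_c1 <- function(sites, allowed = "C") {
  stopifnot(is.data.frame(sites), all(c("c1", "rank") %in% names(sites)))
  if (length(allowed) == 0) abort("`allowed` must name at least one residue")
  sites[sites$c1 %in% toupper(allowed), , drop = FALSE]
}

#' Read or normalize a secondary-structure track
#'
#' Accepts a character vector of per-residue labels, a single string of
#' labels, or a path to a file holding either one label string per line
#' (concatenated) or a TSV with a structure column. Eight-class DSSP codes
#' are collapsed to three states: G/H/I to H, E/B to E, everything else
#' (including `-`, `.`, blanks, S, T, C) to C.
#'
#' @param x Track, label string, or file path.
#' @return Character vector of single-letter H/E/C labels.
#' @export
read_structure_track <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    lines <- readLines(x)
    lines <- trimws(lines[nzchar(trimws(lines))])
    if (length(lines) > 0 && grepl("\t", lines[[1]])) {
      tab <- readr::read_tsv(x, col_types = readr::cols(), progress = FALSE)
      col <- intersect(c("structure", "ss", "label"), names(tab))
      if (length(col) == 0) abort("structure TSV needs a 'structure' (or 'ss'/'label') column")
      x <- tab[[col[[1]]]]
    } else {
      x <- paste(lines, collapse = "")
    }
  }
  if (is.character(x) && length(x) == 1 && nchar(x) > 1) {
    x <- strsplit(x, "")[[1]]
  }
  collapse_dssp(toupper(as.character(x)))
}

#' Collapse DSSP 8-class codes to 3 states
#'
#' @param labels Character vector of single-letter codes.
#' @return Vector over `c("H", "E", "C")`.
#' @export
collapse_dssp <- function(labels) {
  out <- rep("C", length(labels))
  out[labels %in% c("G", "H", "I")] <- "H"
  out[labels %in% c("E", "B")] <- "E"
  out
}

# majority 3-state label over a window; ties resolve to NON STRUCTED
majority_structure <- function(labels) {
  counts <- c(H = sum(labels == "H"), E = sum(labels == "E"), C = sum(labels == "C"))
  top <- counts[counts == max(counts)]
  if (length(top) > 1) return("NON STRUCTED")
  switch(names(top), H = "ALFA-HELIX", E = "BETA-SHEET", C = "NON STRUCTED")
}

#' Annotate one or more sites with a secondary-structure label
#'
#' The label is the majority three-state class over the six window residues
#' (H to `"ALFA-HELIX"`, E to `"BETA-SHEET"`, C to `"NON STRUCTED"`); ties
#' resolve to `"NON STRUCTED"`. Structure is annotation only and never
#' enters the numeric score.
#'
#' @param sites A scan result (or any data frame with a `k` column).
#' @param track A structure track accepted by [read_structure_track()],
#'   aligned to the scanned protein.
#' @param protein_length Length of the scanned protein, used to validate the
#'   track; inferred from the largest `k` if omitted.
#' @return `sites` with a `structure` column.
#' @export
annotate_structure <- function(sites, track, protein_length = NULL) {
  stopifnot(is.data.frame(sites), "k" %in% names(sites))
  track <- read_structure_track(track)
  needed <- protein_length %||% (max(sites$k) + 3)
  if (length(track) < needed) {
    abort(sprintf("structure track length (%d) shorter than required (%d)",
                  length(track), needed))
  }
  if (!is.null(protein_length) && length(track) != protein_length) {
    abort(sprintf("structure track length (%d) does not match protein length (%d)",
                  length(track), protein_length))
  }
  sites$structure <- vapply(sites$k, function(k) majority_structure(track[(k - 2):(k + 3)]),
                            character(1))
  sites
}

#' Select top-ranked candidates and a negative control
#'
#' Picks the `n` best-ranked sites that satisfy the C+1 constraint as
#' experimental candidates, plus one constraint-failing site as a negative
#' control for the splicing reaction (by default the lowest-scoring failing
#' site; override with `negative_control`). Testing at least three
#' high-scoring sites with a fixed catalytic C+1 residue is recommended, as
#' local conformation can still defeat a site that looks optimal on
#' sequence alone.
#'
#' @param sites A scan result from [scan_split_sites()].
#' @param n Number of candidates (default 3).
#' @param allowed_c1 Allowed C+1 residues (default `"C"`).
#' @param negative_control Optional split position `k` to force as the
#'   negative control; it is flagged (with a warning) if it passes the C+1
#'   constraint and would therefore not be a clean control.
#' @return The selected rows with an added `role` column
#'   (`"candidate"` / `"negative_control"`), candidates first.
#' @export
select_candidates <- function(sites, n = 3, allowed_c1 = "C",
                              negative_control = NULL) {
  stopifnot(is.data.frame(sites), n >= 1)
  passing <- filter_c1(sites, allowed_c1)
  passing <- passing[order(passing$rank), , drop = FALSE]
  if (nrow(passing) < n) {
    warn(sprintf("only %d site(s) pass the C+1 constraint (requested %d)",
                 nrow(passing), n))
  }
  cand <- head(passing, n)
  failing <- sites[!sites$c1 %in% toupper(allowed_c1), , drop = FALSE]
  if (is.null(negative_control)) {
    neg <- failing[order(failing$score, failing$k), , drop = FALSE]
    neg <- head(neg, 1)
  } else {
    neg <- sites[sites$k == negative_control, , drop = FALSE]
    if (nrow(neg) == 0) abort(sprintf("no site at position %d", negative_control))
    if (neg$passes_c1[[1]]) {
      warn(sprintf("negative control at %d passes the C+1 constraint", negative_control))
    }
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(cand, role = "candidate"),
    dplyr::mutate(neg, role = "negative_control")
  )
  as_tibble(out)
}

#' Write a ranked split-site report
#'
#' Tab-separated report with the conventional columns `Rating position`,
#' `Sequence`, `Site score` (2 decimals), `Site position` (`"k/k+1"`) and
#' `Secondary structure`, sorted by rank.
#'
#' @param sites A scan result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  stopifnot(is.data.frame(sites))
  out <- tibble(
    `Rating position` = sites$rank,
    Sequence = sites$window,
    `Site score` = sprintf("%.2f", sites$score),
    `Site position` = sites$site,
    `Secondary structure` = if ("structure" %in% names(sites)) sites$structure else ""
  )
  out <- out[order(out$`Rating position`), , drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Plot split-site scores along the protein
#'
#' @param object A `split_scan` result.
#' @param top Label the `top` best-ranked sites with their windows.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot split_scan
#' @export
autoplot.split_scan <- function(object, top = 3, ...) {
  lab <- object[object$rank <= top, , drop = FALSE]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passes_c1), size = 1.4) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$window),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1b7837", `FALSE` = "grey40"),
                                 name = "C+1 allowed") +
    ggplot2::labs(x = "split position k (break between k and k+1)",
                  y = "site score") +
    ggplot2::theme_minimal()
}
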