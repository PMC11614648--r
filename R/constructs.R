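#' Design precursor constructs for one split site
#'
#' Builds the two trans-splicing precursor open reading frames for a target
#' protein split between residues `k` and `k+1`:
#' * N-precursor: `extein[1..k] ++ N-intein ++ tag`
#' * C-precursor: `C-intein ++ extein[k+1..N] ++ tag`
#'
#' plus the controls used to validate the reaction: the full-length target
#' (positive control) and the two tag-less extein halves without inteins
#' (self-assembly control). Tags sit at the C-terminus of both precursors;
#' an optional linker is inserted between extein and intein half. A warning
#' is raised when the extein residue at C+1 (residue `k+1`) is not in the
#' intein's allowed set, since splicing is then expected to fail.
#'
#' @param protein Target protein (string or data frame with `seq`).
#' @param k Split position (break between residues k and k+1).
#' @param intein One registry row (see [read_intein_registry()]) or a list
#'   with `name`, `n_intein`, `c_intein` and optionally `allowed_c1`.
#' @param tag C-terminal tag peptide for both precursors (default 6xHis);
#'   use `""` for tag-less constructs.
#' @param linker Optional linker between extein and intein half (default none).
#' @param id Identifier stem for the products (default `"target"`).
#' @return A `construct_set` object; see [predict_products()] and the
#'   `tidy()` method.
#' @examples
#' cs <- design_constructs(gfp_protein(), 69, dnae_registry()[2, ])
#' predict_products(cs)
#' @export
design_constructs <- function(protein, k, intein, tag = "HHHHHH", linker = "",
                              id = "target") {
  seq <- as_sequence(protein)
  check_protein_alphabet(seq)
  n <- nchar(seq)
  if (length(k) != 1 || k < 1 || k >= n) {
    abort(sprintf("split position must be in [1, %d]", n - 1))
  }
  if (is.data.frame(intein)) {
    if (nrow(intein) != 1) abort("`intein` must be a single registry row")
    intein <- as.list(intein)
    intein$allowed_c1 <- unlist(intein$allowed_c1)
  }
  for (f in c("name", "n_intein", "c_intein")) {
    if (is.null(intein[[f]])) abort(sprintf("`intein` is missing field '%s'", f))
  }
  allowed_c1 <- toupper(intein$allowed_c1 %||% "C")
  tag <- toupper(tag %||% "")
  linker <- toupper(linker %||% "")
  ext_n <- substr(seq, 1, k)
  ext_c <- substr(seq, k + 1, n)
  c1 <- substr(seq, k + 1, k + 1)
  if (!c1 %in% allowed_c1) {
    warn(sprintf(
      "extein residue %d ('%s') at C+1 is not in the allowed set {%s} for %s; splicing is expected to fail",
      k + 1, c1, paste(allowed_c1, collapse = ","), intein$name))
  }
  out <- list(
    id = id,
    split_k = k,
    c1 = c1,
    c1_ok = c1 %in% allowed_c1,
    intein_name = intein$name,
    allowed_c1 = allowed_c1,
    tag = tag,
    linker = linker,
    target = seq,
    n_extein = ext_n,
    c_extein = ext_c,
    n_intein = toupper(intein$n_intein),
    c_intein = toupper(intein$c_intein),
    n_precursor = paste0(ext_n, linker, toupper(intein$n_intein), tag),
    c_precursor = paste0(toupper(intein$c_intein), linker, ext_c, tag),
    control_full = seq,
    control_no_intein = c(n_half = ext_n, c_half = ext_c),
    advisory = paste(
      "Dose the two precursors at an N:C mass ratio of about 2:1 to compensate",
      "for unequal expression of the halves and limit unspliced products.")
  )
  class(out) <- "construct_set"
  out
}

#' Predicted reaction products and their sizes
#'
#' Lists the species expected on a gel for one construct set: both
#' precursors, the spliced full-length extein product, and the excised
#' intein (N-half ++ C-half), with average molecular weights.
#'
#' @param construct_set A [design_constructs()] result.
#' @return A tibble with columns `species`, `seq`, `length`, `mw_da`,
#'   `mw_kda`.
#' @export
predict_products <- function(construct_set) {
  stopifnot(inherits(construct_set, "construct_set"))
  cs <- construct_set
  species <- tibble(
    species = c("n_precursor", "c_precursor", "spliced_product", "excised_intein"),
    seq = c(cs$n_precursor, cs$c_precursor, cs$target,
            paste0(cs$n_intein, cs$c_intein))
  )
  species$length <- nchar(species$seq)
  species$mw_da <- protein_mw(species$seq)
  species$mw_kda <- species$mw_da / 1000
  species
}

#' @export
print.construct_set <- function(x, ...) {
  cat(sprintf("<construct_set> %s split at %d/%d (intein %s, C+1 '%s'%s)\n",
              x$id, x$split_k, x$split_k + 1, x$intein_name, x$c1,
              if (x$c1_ok) "" else " - NOT allowed"))
  cat(sprintf("  N-precursor: %4d aa  (extein 1..%d + %s_N%s)\n",
              nchar(x$n_precursor), x$split_k, x$intein_name,
              if (nzchar(x$tag)) " + tag" else ""))
  cat(sprintf("  C-precursor: %4d aa  (%s_C + extein %d..%d%s)\n",
              nchar(x$c_precursor), x$intein_name, x$split_k + 1,
              nchar(x$target), if (nzchar(x$tag)) " + tag" else ""))
  cat(sprintf("  spliced product: %d aa, %.1f kDa\n",
              nchar(x$target), protein_mw(x$target) / 1000))
  invisible(x)
}

#' Tidy a construct set into one row per sequence component
#'
#' @param x A `construct_set`.
#' @param ... Unused.
#' @return A tibble with columns `role`, `id`, `seq`, `length`, `mw_da`.
#' @method tidy construct_set
#' @export
tidy.construct_set <- function(x, ...) {
  out <- tibble(
    role = c("n_precursor", "c_precursor", "control_full",
             "control_n_half", "control_c_half"),
    id = paste(x$id, c("N-precursor", "C-precursor", "full-length control",
                       "N-half (no intein, no tag)", "C-half (no intein, no tag)"),
               sep = " "),
    seq = c(x$n_precursor, x$c_precursor, x$control_full,
            x$control_no_intein[["n_half"]], x$control_no_intein[["c_half"]])
  )
  out$length <- nchar(out$seq)
  out$mw_da <- protein_mw(out$seq)
  out
}
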