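#' Generate a random protein sequence
#'
#' Residues drawn uniformly from the 20-letter alphabet. With a `seed` the
#' output is reproducible and the caller's RNG state is untouched.
#'
#' @param length Number of residues (>= 1).
#' @param seed Optional integer seed.
#' @param id Record identifier.
#' @return A one-row tibble (`id`, `seq`, `length`), pipeable into the
#'   scanning functions.
#' @export
sim_protein <- function(length, seed = NULL, id = "sim_protein") {
  stopifnot(length >= 1)
  draw <- function() paste(sample(AA_ALPHABET_20, length, replace = TRUE),
                           collapse = "")
  seq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(id = id, seq = seq, length = nchar(seq))
}

#' Generate a synthetic extein-impact matrix
#'
#' Cell values are independent Gaussians with standard deviation
#' `effect_sd`. Optionally a 6-residue window is "planted": its residue at
#' each position receives an additional `planted_bonus`, which makes any
#' site showing exactly that window dominate the scan (a site must match
#' all six positions to collect the full bonus).
#'
#' @param effect_sd Standard deviation of cell values (>= 0; default 1).
#' @param planted_window Optional 6-mer to make rank 1.
#' @param planted_bonus Per-position bonus for the planted window
#'   (default 50; with unit effect_sd this guarantees dominance).
#' @param seed Optional integer seed.
#' @return An [impact_matrix()] with synthetic provenance metadata.
#' @export
sim_impact_matrix <- function(effect_sd = 1, planted_window = NULL,
                              planted_bonus = 50, seed = NULL) {
  stopifnot(effect_sd >= 0)
  if (!is.null(planted_window)) {
    planted_window <- toupper(planted_window)
    if (nchar(planted_window) != 6) abort("`planted_window` must be 6 residues")
    check_protein_alphabet(planted_window)
  }
  draw <- function() {
    m <- matrix(stats::rnorm(20 * 6, sd = effect_sd), nrow = 20,
                dimnames = list(AA_ALPHABET_20, IMPACT_POSITIONS))
    if (!is.null(planted_window)) {
      res <- strsplit(planted_window, "")[[1]]
      m[cbind(res, IMPACT_POSITIONS)] <- m[cbind(res, IMPACT_POSITIONS)] + planted_bonus
    }
    m
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  impact_matrix(m, family = "synthetic",
                source = sprintf("sim_impact_matrix(effect_sd=%g%s)", effect_sd,
                                 if (is.null(planted_window)) "" else
                                   paste0(", planted=", planted_window)))
}

#' Generate synthetic dose-response data
#'
#' Responses follow a four-parameter logistic mean with additive Gaussian
#' noise. The default dose ladder is the six-step AAV transduction series
#' 5e3, 1e4, 2e4, 5e4, 1e5, 2e5 viral genomes per cell, and the default
#' parameters describe a transduction assay rising from about 2% to 90%
#' positive cells with inflection near 4e4 Vg/cell.
#'
#' @param a,d,c,b 4PL parameters (low asymptote, high asymptote,
#'   inflection dose, Hill slope).
#' @param doses Dose vector.
#' @param noise_sd Gaussian noise standard deviation on the response
#'   (default 0).
#' @param seed Optional integer seed.
#' @return A tibble (`dose`, `response`).
#' @export
sim_dose_response <- function(a = 2, d = 90, c = 4e4, b = 1.5,
                              doses = c(5e3, 1e4, 2e4, 5e4, 1e5, 2e5),
                              noise_sd = 0, seed = NULL) {
  stopifnot(all(doses > 0), noise_sd >= 0, c > 0)
  mean_y <- d + (a - d) / (1 + (doses / c)^b)
  draw <- function() mean_y + stats::rnorm(length(doses), sd = noise_sd)
  y <- if (noise_sd == 0) mean_y
       else if (is.null(seed)) draw()
       else withr::with_seed(seed, draw())
  tibble(dose = doses, response = y)
}

#' Generate a synthetic qPCR dilution series
#'
#' Threshold cycles follow `ct = intercept + slope * log10(copies)` with
#' `slope = -1/log10(1 + efficiency)`, plus Gaussian noise, over a
#' ten-fold serial dilution. The default series spans 1e4 to 1e9 copies in
#' six levels with three replicates each, emulating a linearized-plasmid
#' standard.
#'
#' @param efficiency Amplification efficiency as a fraction (> 0; 1.0 is
#'   perfect doubling).
#' @param intercept Ct at one copy (default 38).
#' @param levels Copy numbers of the dilution levels.
#' @param reps Replicates per level (default 3).
#' @param noise_sd Gaussian Ct noise (default 0).
#' @param seed Optional integer seed.
#' @return A tibble (`copies`, `replicate`, `ct`).
#' @export
sim_standard_curve <- function(efficiency = 0.92, intercept = 38,
                               levels = 10^(4:9), reps = 3, noise_sd = 0,
                               seed = NULL) {
  if (efficiency <= 0) abort("`efficiency` must be positive")
  stopifnot(all(levels > 0), reps >= 1, noise_sd >= 0)
  slope <- -1 / log10(1 + efficiency)
  grid <- tidyr::expand_grid(copies = sort(levels, decreasing = TRUE),
                             replicate = seq_len(reps))
  mean_ct <- intercept + slope * log10(grid$copies)
  draw <- function() mean_ct + stats::rnorm(nrow(grid), sd = noise_sd)
  ct <- if (noise_sd == 0) mean_ct
        else if (is.null(seed)) draw()
        else withr::with_seed(seed, draw())
  tibble(copies = grid$copies, replicate = grid$replicate, ct = ct)
}
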