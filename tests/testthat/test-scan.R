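zero_matrix <- function() {
  impact_matrix(matrix(0, nrow = 20, ncol = 6,
                       dimnames = list(AA20, c("N-3", "N-2", "N-1",
                                               "C+1", "C+2", "C+3"))))
}

test_that("site enumeration yields N-5 complete windows", {
  expect_equal(enumerate_split_sites("ACDEFG"), 3L)
  expect_equal(length(enumerate_split_sites(gfp_protein())), 233L)
  expect_warning(out <- enumerate_split_sites("ACDEF"), "length 5")
  expect_equal(out, integer(0))
  withr::local_seed(5)
  for (n in sample(6:200, 10)) {
    expect_equal(length(enumerate_split_sites(random_protein_seq(n))), n - 5)
  }
})

test_that("windows are residues k-2..k+3 and expose the C+1 residue", {
  expect_equal(site_window("ABCDEFG", 3), "ABCDEF")
  gfp <- gfp_protein()
  expect_equal(site_window(gfp, 69), "GVQCFS")
  expect_equal(site_window(gfp, 47), "KFICTT")
  expect_equal(site_window(gfp, 55), "LPVPWP")
  expect_equal(site_window(gfp, 17), "LVELDG")
  expect_error(site_window(gfp, 2), "out of range")
  expect_error(site_window(gfp, 236), "out of range")
})

test_that("window scores are per-position sums over the matrix", {
  expect_equal(score_window("MKVLIW", zero_matrix()), 0)
  ones <- impact_matrix(matrix(1, nrow = 20, ncol = 6,
                               dimnames = list(AA20, c("N-3", "N-2", "N-1",
                                                       "C+1", "C+2", "C+3"))))
  expect_equal(score_window("MKVLIW", ones), 6)
  expect_error(score_window("MKVLI", ones), "6 residues")
  expect_error(score_window("MKVLIX", ones), "non-canonical")
  expect_equal(score_window("MKVLIX", ones, strict = FALSE), 5)
})

test_that("scan agrees with a brute-force oracle on random inputs", {
  withr::local_seed(101)
  for (i in 1:60) {
    seq <- random_protein_seq(sample(6:50, 1))
    lut <- random_matrix_tbl()
    mat <- impact_matrix(lut)
    got <- scan_split_sites(seq, mat)
    want <- oracle_scan(seq, lut)
    expect_equal(got$k, want$k)
    expect_equal(got$window, want$window)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$rank, seq_len(nrow(want)))
  }
})

test_that("every scanned window satisfies the C+1 identity", {
  withr::local_seed(17)
  seq <- random_protein_seq(80)
  res <- scan_split_sites(seq, zero_matrix())
  expect_equal(res$c1, substr(res$window, 4, 4))
  expect_equal(res$c1, substring(seq, res$k + 1, res$k + 1))
})

test_that("uniform matrices tie-break by ascending position", {
  seq <- random_protein_seq(40)
  res <- scan_split_sites(seq, zero_matrix())
  expect_equal(res$k, 3:(nchar(seq) - 3))
  expect_true(all(res$score == 0))
})

test_that("adding a constant to all cells shifts scores by 6c and keeps ranks", {
  withr::local_seed(23)
  seq <- random_protein_seq(45)
  lut <- random_matrix_tbl()
  shift <- 3.7
  base <- scan_split_sites(seq, impact_matrix(lut))
  shifted <- scan_split_sites(seq, impact_matrix(lut + shift))
  expect_equal(shifted$k, base$k)
  expect_equal(shifted$score, base$score + 6 * shift, tolerance = 1e-9)
})

test_that("the C+1 filter keeps order and ranks, and can empty the set", {
  mat <- sim_impact_matrix(seed = 4)
  res <- scan_split_sites(gfp_protein(), mat)
  kept <- filter_c1(res, "C")
  expect_true(all(kept$c1 == "C"))
  expect_true(!is.unsorted(match(kept$rank, res$rank)))
  expect_equal(nrow(filter_c1(res, AA20)), nrow(res))
  absent <- setdiff(AA20, unique(res$c1))
  if (length(absent) > 0) expect_equal(nrow(filter_c1(res, absent[1])), 0)
})

test_that("structure annotation takes the majority label with ties unstructured", {
  seq <- random_protein_seq(20)
  all_h <- strrep("H", 20)
  res <- scan_split_sites(seq, zero_matrix(), structure = all_h)
  expect_true(all(res$structure == "ALFA-HELIX"))
  # windows drawn over an HHHEEC / HHHEEE boundary
  track <- c("H", "H", "H", "E", "E", "C")
  sites <- tibble::tibble(k = 3)
  expect_equal(annotate_structure(sites, track, protein_length = 6)$structure,
               "ALFA-HELIX")
  track_tie <- c("H", "H", "H", "E", "E", "E")
  expect_equal(annotate_structure(sites, track_tie, protein_length = 6)$structure,
               "NON STRUCTED")
  expect_error(scan_split_sites(seq, zero_matrix(), structure = "HEC"),
               "track length")
})

test_that("DSSP 8-class codes collapse to 3 states", {
  expect_equal(collapse_dssp(c("G", "H", "I", "E", "B", "S", "T", "-", "C")),
               c("H", "H", "H", "E", "E", "C", "C", "C", "C"))
})

test_that("candidate selection returns top passing sites plus a failing control", {
  mat <- sim_impact_matrix(seed = 9, planted_window = "GVQCFS")
  res <- scan_split_sites(gfp_protein(), mat)
  sel <- select_candidates(res, n = 2)
  cand <- sel[sel$role == "candidate", ]
  neg <- sel[sel$role == "negative_control", ]
  expect_equal(nrow(cand), 2)
  expect_true(all(cand$c1 == "C"))
  expect_equal(cand$window[1], "GVQCFS")
  expect_equal(nrow(neg), 1)
  expect_false(neg$passes_c1)
  # forced override is accepted and flagged non-passing
  sel2 <- select_candidates(res, n = 2, negative_control = 128)
  expect_equal(sel2$window[sel2$role == "negative_control"], "KGIDFK")
  expect_false(sel2$passes_c1[sel2$role == "negative_control"])
})

test_that("requesting more candidates than passing sites warns and returns all", {
  seq <- "AAAWAAAWAAAW" # no cysteines anywhere
  res <- scan_split_sites(seq, zero_matrix())
  expect_warning(sel <- select_candidates(res, n = 3), "0 site")
  expect_equal(sum(sel$role == "candidate"), 0)
})

test_that("site reports round-trip scores at 2 decimals", {
  mat <- sim_impact_matrix(seed = 2)
  res <- scan_split_sites(gfp_protein(), mat,
                          structure = strrep("C", 238))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_report(res, path)
  back <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  expect_equal(nrow(back), nrow(res))
  expect_equal(names(back), c("Rating position", "Sequence", "Site score",
                              "Site position", "Secondary structure"))
  expect_equal(back$`Rating position`, sort(res$rank))
  merged <- merge(back, res, by.x = "Rating position", by.y = "rank")
  expect_equal(as.numeric(merged$`Site score`), round(merged$score, 2),
               tolerance = 1e-9)
  rank1 <- back[back$`Rating position` == 1, ]
  expect_match(rank1$`Site position`, "^\\d+/\\d+$")
})
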