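# Independent oracles and small generators used across tests.
# None of these call the package's own scanning/merging code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

random_dna_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                    collapse = "")

random_matrix_tbl <- function(sd = 5) {
  m <- matrix(rnorm(120, sd = sd), nrow = 20,
              dimnames = list(AA20, c("N-3", "N-2", "N-1", "C+1", "C+2", "C+3")))
  m
}

# brute-force split-site oracle: score every window independently with plain
# indexing arithmetic, then order by (-score, k)
oracle_scan <- function(seq, lookup) {
  n <- nchar(seq)
  if (n < 6) return(data.frame(k = integer(), window = character(), score = numeric()))
  ks <- 3:(n - 3)
  rows <- lapply(ks, function(k) {
    w <- substr(seq, k - 2, k + 3)
    res <- strsplit(w, "")[[1]]
    s <- 0
    for (j in 1:6) s <- s + lookup[res[j], j]
    data.frame(k = k, window = w, score = s)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$k), , drop = FALSE]
}

# naive substring search oracle
oracle_substring <- function(seq, pattern) {
  n <- nchar(seq); m <- nchar(pattern)
  hits <- integer(0)
  if (m > n) return(hits)
  for (i in 1:(n - m + 1)) {
    if (substr(seq, i, i + m - 1) == pattern) hits <- c(hits, i)
  }
  hits
}

# 4PL mean function, written independently of the package
oracle_4pl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)
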