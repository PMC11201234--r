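# Independent brute-force oracles, kept free of the package's own code paths.

# Benjamini-Hochberg step-up from the definition: sort, scale by n/rank,
# enforce monotonicity by cumulative minimum from the largest, clip at 1.
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  scaled <- p[ord] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(pmin(scaled, 1))))
  adj <- numeric(n)
  adj[ord] <- adj_sorted
  adj
}

# upper-tail hypergeometric by direct enumeration of the pmf
brute_hyper_tail <- function(overlap, set_size, query_size, universe) {
  ii <- overlap:min(set_size, query_size)
  sum(choose(set_size, ii) * choose(universe - set_size, query_size - ii)) /
    choose(universe, query_size)
}

# small deterministic count matrix: 4 genes x 5 samples (3 specimen, 2 control)
make_test_counts <- function() {
  m <- matrix(c(
    10, 12,  8, 11,  9,
    40, 38, 45,  5,  4,
     0,  0,  0,  0,  0,
     5,  6,  4, 50, 55), nrow = 4, byrow = TRUE,
    dimnames = list(c("GA", "GB", "GC", "GD"),
                    c("s1", "s2", "s3", "c1", "c2")))
  md <- data.frame(sample_id = colnames(m),
                   group = c("specimen", "specimen", "specimen",
                             "control", "control"),
                   patient_id = c("p1", "p1", "p2", NA, NA))
  count_matrix(m, md)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
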