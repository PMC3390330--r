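# Shared test helpers: exhaustive matchings and small structure builders.

# All perfect matchings of points 1..2n as a list of two-column matrices.
all_matchings <- function(n) {
  rec <- function(pts) {
    if (length(pts) == 0L) return(list(matrix(integer(0), ncol = 2L)))
    a <- pts[1L]
    out <- list()
    for (k in seq_along(pts)[-1L]) {
      for (m in rec(pts[-c(1L, k)]))
        out[[length(out) + 1L]] <- rbind(c(a, pts[k]), m)
    }
    out
  }
  rec(seq_len(2L * n))
}

# Random structure: plant a few motifs through the generator.
random_fixture <- function(seed, tokens = c("ABAB", "ABACBC", "ABCABC")) {
  k <- 1L + seed %% 3L
  motifs <- lapply(seq_len(k), function(i)
    list(token = tokens[1L + (seed + i) %% length(tokens)],
         stem = c(1L, 4L), bulge = 0.15))
  generate_fixture(motifs, seed = seed, decoy_hairpins = seed %% 2L)
}
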