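# Independent oracles and random-instance builders used across test files.

# Hypergeometric upper tail by direct binomial-coefficient arithmetic
# (exact in double precision for N <= 30); independent of the log-space
# implementation under test.
chooseSumTail <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Hypergeometric upper tail by full enumeration of every draw of size n
# from the universe (tiny N only).
enumTail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Random normalized gene-set library
randomLibrary <- function(nSets = 5L, poolSize = 50L) {
  pool <- sprintf("GENE%03d", seq_len(poolSize))
  sets <- lapply(seq_len(nSets), function(i) {
    sample(pool, sample(2:12, 1L))
  })
  names(sets) <- sprintf("SET%02d", seq_len(nSets))
  GeneSetLibrary(sets, sourceTag = "random")
}

# Small cleaned interactome from a bare pair list
pairNet <- function(a, b) {
  Interactome(a = a, b = b, publication = rep("PMID:1", length(a)),
              system = rep("test", length(a)))
}

# strip row names for frame comparisons
bareDf <- function(d) { rownames(d) <- NULL; d }
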