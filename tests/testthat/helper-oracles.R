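# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force enumeration and direct arithmetic
# only.

# all ways to assign n labelled items to blocks 0..k (block 0 = S0 may be
# empty, blocks 1..k must be non-empty, blocks 1..k unordered): counts
# distinct partitions by canonical signature
brute_count_partitions <- function(n, k) {
  grids <- rep(list(0:k), n)
  assignments <- do.call(expand.grid, grids)
  seen <- new.env(hash = TRUE)
  count <- 0L
  for (r in seq_len(nrow(assignments))) {
    lab <- as.integer(assignments[r, ])
    if (length(unique(lab[lab > 0])) != k) next
    s0 <- which(lab == 0)
    blocks <- lapply(sort(unique(lab[lab > 0])), function(b) which(lab == b))
    sig <- paste(
      paste(s0, collapse = ","),
      paste(sort(vapply(blocks, function(b) paste(b, collapse = ","), "")),
            collapse = ";"),
      sep = "|"
    )
    if (!exists(sig, envir = seen)) {
      assign(sig, TRUE, envir = seen)
      count <- count + 1L
    }
  }
  count
}

# Stirling number of the second kind by the explicit inclusion-exclusion
# sum, in doubles (exact for small n)
brute_stirling2 <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  i <- 0:k
  sum((-1)^i * choose(k, i) * (k - i)^n) / factorial(k)
}

# brute-force partition count of n labelled items into exactly k non-empty
# unordered blocks: surjective assignments divided by k! relabellings
brute_stirling2_enum <- function(n, k) {
  assignments <- do.call(expand.grid, rep(list(seq_len(k)), n))
  surjective <- apply(assignments, 1, function(lab) length(unique(lab)) == k)
  sum(surjective) / factorial(k)
}

# interval intersection-over-union by explicit position enumeration
brute_iou <- function(s1, e1, s2, e2) {
  a <- seq.int(s1, length.out = max(0, e1 - s1))
  b <- seq.int(s2, length.out = max(0, e2 - s2))
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

# cached enumeration of the 2135 order-2 representatives (computed once
# per test session)
reps_cache <- new.env()
get_reps <- function() {
  if (is.null(reps_cache$reps)) reps_cache$reps <- enumerate_restricted(2)
  reps_cache$reps
}

# random restricted-SSR spec (uniform over partitions x injections, not
# over classes) for property tests
random_ssr_spec <- function() {
  free <- canonical_lmers(2)$free_pairs$canonical
  k <- sample(1:4, 1)
  repeat {
    lab <- sample(0:k, length(free), replace = TRUE)
    if (length(unique(lab[lab > 0])) == k) break
  }
  parts <- c(list(free[lab == 0]),
             lapply(sort(unique(lab[lab > 0])), function(b) free[lab == b]))
  inj <- sample(c("A", "C", "G", "T"), k)
  ssr_spec(parts, inj, order = 2)
}

# uniform integer in [lo, hi], safe when lo == hi
rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

random_dna_string <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
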