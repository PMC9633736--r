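test_that("canonical_lmers splits self-complementary words from free pairs", {
  cl2 <- canonical_lmers(2)
  expect_setequal(cl2$self_rc, c("AT", "TA", "GC", "CG"))
  expect_equal(cl2$free_pairs$canonical, c("AA", "AC", "AG", "CA", "CC", "GA"))
  expect_equal(cl2$free_pairs$partner, c("TT", "GT", "CT", "TG", "GG", "TC"))
  cl1 <- canonical_lmers(1)
  expect_length(cl1$self_rc, 0)
  expect_equal(nrow(cl1$free_pairs), 2)
  cl3 <- canonical_lmers(3)
  expect_length(cl3$self_rc, 0)
  expect_equal(nrow(cl3$free_pairs), 32)
  # every pair is genuinely a reverse-complement pair, canonical first
  expect_equal(revcomp(cl3$free_pairs$canonical), cl3$free_pairs$partner)
  expect_true(all(cl3$free_pairs$canonical < cl3$free_pairs$partner))
})

test_that("free_input_count follows the parity formula and matches enumeration", {
  expect_equal(free_input_count(2), 6)
  expect_equal(free_input_count(3), 32)
  expect_equal(free_input_count(4), 120)
  for (l in 1:4) {
    expect_equal(free_input_count(l), nrow(canonical_lmers(l)$free_pairs))
  }
})

test_that("count_partitions matches the brute-force partition enumerator", {
  brute <- vapply(1:4, function(k) brute_count_partitions(6, k), 0L)
  mine <- vapply(1:4, function(k) as.numeric(count_partitions(2, k)), 0)
  expect_equal(mine, as.numeric(brute))
  expect_equal(mine[1], 63)
  expect_equal(mine[2], 301)
  # k above the number of free inputs is impossible
  expect_equal(as.numeric(count_partitions(2, 4)), brute_count_partitions(6, 4))
})

test_that("injection classes are found by enumeration and grouping", {
  o <- vapply(1:4, injection_class_count, 1L)
  expect_equal(o, c(1L, 2L, 3L, 3L))
  expect_equal(sum(o), 9L)
})

test_that("the restricted count combines partitions and injection classes", {
  n2 <- count_restricted(2)
  expect_equal(as.numeric(n2), 2135)
  # independent recomputation of the sum from its pieces
  pieces <- vapply(1:4, function(k) {
    as.numeric(count_partitions(2, k)) * injection_class_count(k)
  }, 0)
  expect_equal(sum(pieces), as.numeric(n2))
})

test_that("higher-order counts are exact and round as printed", {
  n3 <- count_restricted(3)
  expect_equal(as.character(n3), "2910383508928417574288")
  expect_equal(bigint_signif(n3), "2.9e+21")
  expect_equal(bigint_signif(unrestricted_count(2)), "1.5e+11")
  expect_equal(bigint_signif(bigint(5)^64), "5.4e+44")
  # order 4: the exact mantissa at two significant figures is 9.4
  expect_equal(substr(bigint_signif(count_restricted(4)), 1, 3), "9.4")
})

test_that("enumeration yields 2135 distinct RC-core-insensitive representatives", {
  reps <- get_reps()
  expect_equal(nrow(reps), 2135)
  expect_equal(length(unique(reps$key)), 2135)
  expect_equal(as.numeric(count_restricted(2)), nrow(reps))
  # spot-check functional properties on a sample
  withr::with_seed(21, idx <- sample(nrow(reps), 100))
  for (i in idx) {
    f <- reps$fn[[i]]
    expect_true(is_rc_core_insensitive(f))
    expect_equal(unname(unclass(f)[c("AT", "TA", "GC", "CG")]), rep("", 4))
  }
  expect_equal(table(reps$k)[["1"]], 63)
  expect_equal(table(reps$k)[["4"]], 420)
})

test_that("enumeration order and representatives are deterministic", {
  reps <- get_reps()
  again <- enumerate_restricted(2)
  expect_equal(reps$id, again$id)
  expect_equal(reps$key, again$key)
  expect_equal(reps$key[1], reduction_key(again$fn[[1]]))
})

test_that("enumeration at higher orders is refused with the count in the message", {
  expect_error(enumerate_restricted(3), "2.9e\\+21")
  expect_error(enumerate_restricted(4), "order 2")
})

test_that("are_equivalent implements the three-condition criterion", {
  spec <- ssr_spec(
    parts = list(character(0), c("AG", "CA"), "CC", c("AA", "AC"), "GA"),
    injection = c("A", "T", "C", "G"), order = 2
  )
  expect_true(are_equivalent(spec, spec))
  # swapping complementary output letters preserves the complement pattern
  swapped <- ssr_spec(
    parts = list(character(0), c("AG", "CA"), "CC", c("AA", "AC"), "GA"),
    injection = c("T", "A", "G", "C"), order = 2
  )
  expect_true(are_equivalent(spec, swapped))
  # moving an l-mer into S0 changes S0, hence never equivalent
  moved <- ssr_spec(
    parts = list("CC", c("AG", "CA"), c("AA", "AC"), "GA"),
    injection = c("A", "T", "G"), order = 2
  )
  expect_false(are_equivalent(spec, moved))
  # different dimension is never equivalent
  flat <- ssr_spec(
    parts = list(character(0), c("AA", "AC", "AG", "CA", "CC", "GA")),
    injection = "A", order = 2
  )
  expect_false(are_equivalent(spec, flat))
})

test_that("equivalence is reflexive, symmetric and transitive on random specs", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      a <- random_ssr_spec()
      b <- random_ssr_spec()
      c <- random_ssr_spec()
      expect_true(are_equivalent(a, a))
      expect_equal(are_equivalent(a, b), are_equivalent(b, a))
      if (are_equivalent(a, b) && are_equivalent(b, c)) {
        expect_true(are_equivalent(a, c))
      }
    }
  })
})

test_that("representatives are pairwise non-equivalent", {
  reps <- get_reps()
  withr::with_seed(41, {
    i <- sample(nrow(reps), 1000, replace = TRUE)
    j <- sample(nrow(reps), 1000, replace = TRUE)
    for (p in seq_along(i)) {
      if (i[p] == j[p]) next
      expect_false(are_equivalent(reps$spec[[i[p]]], reps$spec[[j[p]]]))
    }
  })
})

test_that("dimension counts the distinct output nucleotides", {
  spec4 <- ssr_spec(
    parts = list(character(0), c("AG", "CA"), "CC", c("AA", "AC"), "GA"),
    injection = c("A", "T", "C", "G"), order = 2
  )
  expect_equal(dimension(spec4), 4)
  flat <- ssr_spec(
    parts = list(character(0), c("AA", "AC", "AG", "CA", "CC", "GA")),
    injection = "A", order = 2
  )
  expect_equal(dimension(flat), 1)
  three <- ssr_spec(
    parts = list(c("CA", "CC", "GA"), "AA", "AC", "AG"),
    injection = c("A", "C", "G"), order = 2
  )
  expect_equal(dimension(three), 3)
})

test_that("materialized specs honour the RC-core completion", {
  spec <- ssr_spec(
    parts = list(character(0), c("AG", "CA"), "CC", c("AA", "AC"), "GA"),
    injection = c("A", "T", "C", "G"), order = 2
  )
  f <- as_reduction(spec)
  expect_equal(unclass(f)[["AA"]], "C")
  expect_equal(unclass(f)[["TT"]], "G")
  expect_equal(unclass(f)[["GA"]], "G")
  expect_equal(unclass(f)[["TC"]], "C")
  expect_equal(unclass(f)[["AT"]], "")
  expect_true(is_rc_core_insensitive(f))
})
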