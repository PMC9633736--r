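# Construction, counting, equivalence and exhaustive enumeration of
# restricted SSRs: reductions that are RC-core-insensitive, represented one
# per equivalence class. A restricted SSR of order l is determined by a
# partition of the free canonical l-mers into S0 (deleted) and k non-empty
# parts S1..Sk, plus an injective assignment of output nucleotides to the
# parts; self-reverse-complement l-mers are forced to the empty output and
# the partner of each free l-mer receives the complementary output.

#' Self-complementary and free canonical l-mers
#'
#' Splits the `4^l` `l`-mers into those equal to their own reverse
#' complement (forced to the empty output in any RC-core-insensitive
#' reduction) and the remaining reverse-complement pairs, each pair ordered
#' lexicographically. The first member of each pair is the free canonical
#' `l`-mer carrying the degree of freedom in defining the window function.
#'
#' @param l Word length.
#' @return A list with `self_rc` (character vector) and `free_pairs`
#'   (tibble with columns `canonical`, `partner`).
#' @examples
#' canonical_lmers(2)
#' @export
canonical_lmers <- function(l) {
  lmers <- all_lmers(l)
  rc <- revcomp(lmers)
  self_rc <- lmers[lmers == rc]
  free <- lmers[lmers < rc]
  tibble_pairs <- tibble::tibble(canonical = free, partner = rc[lmers < rc])
  list(self_rc = self_rc, free_pairs = tibble_pairs)
}

#' Degrees of freedom in an order-l RC-core-insensitive reduction
#'
#' The number `i(l)` of reverse-complement pairs of non-self-complementary
#' `l`-mers: `4^l / 2` for odd `l` and `(4^l - 4^(l/2)) / 2` for even `l`
#' (for even `l` there are `4^(l/2)` palindromic self-complementary words).
#'
#' @param l Word length.
#' @return Integer count.
#' @examples
#' free_input_count(2) # 6
#' @export
free_input_count <- function(l) {
  stopifnot(l >= 1)
  if (l %% 2 == 1) 4^l / 2 else (4^l - 4^(l / 2)) / 2
}

#' Partition counts for restricted SSRs
#'
#' `count_partitions(l, k)` is the number `C(l, k)` of ways to partition
#' the `i(l)` free canonical `l`-mers into `S0, S1, ..., Sk` with
#' `S1..Sk` non-empty: summing over the number `j` assigned to `S0`,
#' the Stirling term for `j = 0`, `choose(i, j)` times a Stirling number
#' for `1 <= j <= i - k`, and zero beyond. Exact arithmetic.
#'
#' @param l Word length.
#' @param k Dimension, 1 to 4.
#' @return A [bigint].
#' @examples
#' as.numeric(count_partitions(2, 1)) # 63
#' @export
count_partitions <- function(l, k) {
  stopifnot(k >= 1, k <= 4)
  i <- free_input_count(l)
  if (k > i) return(bigint(0))
  total <- stirling2(i, k)
  j <- 1
  while (j <= i - k) {
    total <- total + big_choose(i, j) * stirling2(i - j, k)
    j <- j + 1
  }
  total
}

#' Equivalence classes of output injections
#'
#' Two restricted SSRs sharing a partition are equivalent when their
#' injections induce the same pattern of Watson-Crick complement relations
#' between parts. `injection_class_count(k)` enumerates all injective maps
#' from `{1..k}` into `{A, C, G, T}`, groups them by that complement
#' pattern and counts the groups; nothing is hard-coded.
#'
#' @param k Dimension, 1 to 4.
#' @return Integer number of classes (`o(k)`).
#' @examples
#' vapply(1:4, injection_class_count, 1L) # 1 2 3 3
#' @export
injection_class_count <- function(k) {
  length(unique(vapply(all_injections(k), iscomp_pattern, "")))
}

# all injective maps {1..k} -> {A,C,G,T}, as character vectors of length k
all_injections <- function(k) {
  stopifnot(k >= 1, k <= 4)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  out <- list()
  for (sub in utils::combn(DNA_BASES, k, simplify = FALSE)) {
    out <- c(out, perms(sub))
  }
  out
}

# canonical encoding of which index pairs (i < j) get complementary outputs
iscomp_pattern <- function(t) {
  k <- length(t)
  if (k == 1) return("")
  pairs <- utils::combn(k, 2)
  flags <- vapply(seq_len(ncol(pairs)), function(c) {
    iscomp(t[pairs[1, c]], t[pairs[2, c]])
  }, TRUE)
  paste0(as.integer(flags), collapse = "")
}

#' Exact count of restricted SSRs
#'
#' Number of equivalence-class representatives of order-`l`
#' RC-core-insensitive reductions: the sum over dimension `k = 1..4` of
#' `C(l, k) * o(k)`, with partition counts from [count_partitions()] and
#' injection-class counts from [injection_class_count()]. Exact for any
#' order (2135 at order 2; astronomically large from order 3 on).
#'
#' @param l Order (`l >= 2`).
#' @return A [bigint].
#' @examples
#' as.numeric(count_restricted(2)) # 2135
#' bigint_signif(count_restricted(3)) # "2.9e+21"
#' @export
count_restricted <- function(l) {
  stopifnot(l >= 2)
  total <- bigint(0)
  for (k in 1:4) {
    total <- total + count_partitions(l, k) * bigint(injection_class_count(k))
  }
  total
}

#' Size of the unrestricted SSR space
#'
#' Every order-`l` window function maps `4^l` inputs to one of 5 outputs,
#' so the unrestricted space has `5^(4^l)` members.
#'
#' @param l Order.
#' @return A [bigint].
#' @examples
#' bigint_signif(unrestricted_count(2)) # "1.5e+11"
#' @export
unrestricted_count <- function(l) bigint(5)^(4^l)

#' Summary table of the counting formula
#'
#' @param l Order.
#' @return A tibble with one row per dimension `k`: `C` (partition count,
#'   as character to stay exact), `o` (injection classes), and attributes
#'   aside, the totals printed by `count_report()`.
#' @export
count_table <- function(l) {
  rows <- lapply(1:4, function(k) {
    C <- count_partitions(l, k)
    o <- injection_class_count(k)
    tibble::tibble(k = k, C = as.character(C), o = o,
                   contribution = as.character(C * bigint(o)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "l") <- l
  attr(out, "i") <- free_input_count(l)
  attr(out, "N") <- as.character(count_restricted(l))
  out
}

# ---- SSR specs and equivalence ---------------------------------------------

#' Construct a restricted-SSR specification
#'
#' @param parts List of character vectors: `S0` first (possibly empty, the
#'   deleted part), then the `k` non-empty parts, each a set of free
#'   canonical `l`-mers.
#' @param injection Character vector of length `k` of distinct nucleotides:
#'   the output letter of each non-`S0` part.
#' @param order Word length `l` (default inferred from the `l`-mers).
#' @return An object of class `ssr_spec`.
#' @export
ssr_spec <- function(parts, injection, order = NULL) {
  stopifnot(is.list(parts), length(parts) >= 2)
  k <- length(parts) - 1L
  if (length(injection) != k) stop("injection must assign one letter per non-S0 part")
  if (anyDuplicated(injection) || !all(injection %in% DNA_BASES)) {
    stop("injection must be an injective map into {A,C,G,T}")
  }
  members <- unlist(parts)
  if (anyDuplicated(members)) stop("parts must be disjoint")
  if (is.null(order)) order <- nchar(members[1])
  free <- canonical_lmers(order)$free_pairs$canonical
  if (!setequal(members, free)) {
    stop("parts must cover exactly the free canonical l-mers (",
         toString(free), ")")
  }
  if (any(vapply(parts[-1], length, 1L) == 0)) stop("S1..Sk must be non-empty")
  parts <- lapply(parts, function(p) sort(p))
  structure(list(order = as.integer(order), parts = parts, injection = injection),
            class = "ssr_spec")
}

#' @export
print.ssr_spec <- function(x, ...) {
  k <- length(x$parts) - 1L
  cat("<ssr_spec> order ", x$order, ", dimension ", k, "\n", sep = "")
  cat("  S0 = {", paste(x$parts[[1]], collapse = ","), "}\n", sep = "")
  for (i in seq_len(k)) {
    cat("  S", i, " = {", paste(x$parts[[i + 1L]], collapse = ","), "} -> ",
        x$injection[i], "\n", sep = "")
  }
  invisible(x)
}

#' Dimension of a restricted SSR
#'
#' The number `k` of distinct nucleotides the window function can output on
#' canonical inputs (1 to 4).
#'
#' @param spec An [ssr_spec].
#' @return Integer.
#' @export
dimension <- function(spec) {
  stopifnot(inherits(spec, "ssr_spec"))
  length(spec$parts) - 1L
}

#' Materialize a spec as a reduction function
#'
#' Expands an [ssr_spec] into the full `4^l` table: members of `S0` and all
#' self-reverse-complement `l`-mers map to the empty output; each member of
#' `Si` maps to its part's output letter and its reverse-complement partner
#' to the complementary letter.
#'
#' @param spec An [ssr_spec].
#' @param name Optional name for the resulting [reduction].
#' @return A [reduction].
#' @export
as_reduction <- function(spec, name = NULL) {
  stopifnot(inherits(spec, "ssr_spec"))
  l <- spec$order
  keys <- all_lmers(l)
  tab <- stats::setNames(rep("", length(keys)), keys)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  k <- length(spec$parts) - 1L
  for (i in seq_len(k)) {
    out <- spec$injection[i]
    for (x in spec$parts[[i + 1L]]) {
      tab[x] <- out
      tab[revcomp(x)] <- comp[[out]]
    }
  }
  reduction(tab, name = name)
}

#' Are two restricted-SSR specifications equivalent?
#'
#' Equivalence of specs of equal dimension `k` requires: identical `S0`;
#' a permutation `pi` of `{1..k}` aligning the parts; and identical
#' Watson-Crick complement patterns between outputs under `pi`. Specs of
#' different dimension (or order) are never equivalent.
#'
#' @param a,b [ssr_spec] objects.
#' @return `TRUE` or `FALSE`.
#' @export
are_equivalent <- function(a, b) {
  stopifnot(inherits(a, "ssr_spec"), inherits(b, "ssr_spec"))
  if (a$order != b$order) return(FALSE)
  k <- dimension(a)
  if (k != dimension(b)) return(FALSE)
  if (!setequal(a$parts[[1]], b$parts[[1]])) return(FALSE)
  key <- function(p) paste(sort(p), collapse = ",")
  akeys <- vapply(a$parts[-1], key, "")
  bkeys <- vapply(b$parts[-1], key, "")
  pi <- match(akeys, bkeys)
  if (anyNA(pi)) return(FALSE)
  if (k == 1) return(TRUE)
  pairs <- utils::combn(k, 2)
  all(vapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    iscomp(a$injection[i], a$injection[j]) ==
      iscomp(b$injection[pi[i]], b$injection[pi[j]])
  }, TRUE))
}

# ---- exhaustive enumeration (order 2) --------------------------------------

# all set partitions of items into exactly k non-empty unlabelled blocks,
# blocks ordered by smallest member: restricted-growth-string enumeration
set_partitions <- function(items, k) {
  n <- length(items)
  if (k > n) return(list())
  out <- list()
  rgs <- integer(n)
  recurse <- function(pos, maxblock) {
    if (pos > n) {
      if (maxblock == k) {
        blocks <- split(items, rgs)
        out[[length(out) + 1L]] <<- unname(blocks)
      }
      return(invisible())
    }
    for (b in seq_len(min(maxblock + 1L, k))) {
      rgs[pos] <<- b
      recurse(pos + 1L, max(maxblock, b))
    }
  }
  recurse(1L, 0L)
  out
}

#' Enumerate all restricted order-2 SSRs
#'
#' Produces exactly one representative of each equivalence class of
#' RC-core-insensitive order-2 reductions: 2135 in total. For every
#' dimension `k`, every split of the 6 free canonical dinucleotides into
#' `S0` plus `k` non-empty parts, and every complement-pattern class of
#' output injections, the representative is the member of the class whose
#' serialized table ([reduction_key()]) is lexicographically smallest.
#' The enumeration order (dimension, then partition encoding, then pattern)
#' is deterministic.
#'
#' Orders above 2 are refused: the restricted space already holds about
#' 2.9e21 classes at order 3.
#'
#' @param l Order; only `l = 2` is supported.
#' @return A tibble with columns `id` (stable identifier), `k`, `partition`
#'   (encoded `S0 | S1 | ...`), `pattern` (complement-pattern string), and
#'   list-columns `spec` ([ssr_spec]) and `fn` ([reduction]).
#' @examples
#' \donttest{
#' reps <- enumerate_restricted(2)
#' nrow(reps) # 2135
#' }
#' @export
enumerate_restricted <- function(l = 2) {
  if (l != 2) {
    stop("enumeration is only tractable at order 2; the restricted space has ",
         bigint_signif(count_restricted(3)), " classes at order 3 and ",
         bigint_signif(count_restricted(4)), " at order 4")
  }
  pairs <- canonical_lmers(2)$free_pairs
  free <- pairs$canonical
  keys16 <- all_lmers(2)
  can_idx <- match(free, keys16)
  par_idx <- match(pairs$partner, keys16)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # serialized table ("-" for the empty output) for a part assignment
  # (0 = S0) of the 6 free pairs under injection t, without object overhead
  fast_key <- function(member_part, t) {
    canon_out <- c("", t)[member_part + 1L]
    tab <- rep("-", 16)
    nz <- canon_out != ""
    tab[can_idx[nz]] <- canon_out[nz]
    tab[par_idx[nz]] <- comp[canon_out[nz]]
    paste0(tab, collapse = "")
  }
  rows <- list()
  for (k in 1:4) {
    injections <- all_injections(k)
    patterns <- vapply(injections, iscomp_pattern, "")
    by_pattern <- split(injections, patterns)
    # subsets of free pairs assigned to S0, from none upward
    for (j in 0:(length(free) - k)) {
      s0_sets <- if (j == 0) list(character(0)) else
        utils::combn(free, j, simplify = FALSE)
      for (s0 in s0_sets) {
        rest <- setdiff(free, s0)
        for (blocks in set_partitions(rest, k)) {
          member_part <- integer(length(free))
          for (b in seq_along(blocks)) {
            member_part[match(blocks[[b]], free)] <- b
          }
          partition_enc <- paste(vapply(c(list(s0), blocks),
                                        function(p) paste(sort(p), collapse = ","), ""),
                                 collapse = " | ")
          for (pi in seq_along(by_pattern)) {
            pat <- names(by_pattern)[pi]
            cands <- by_pattern[[pi]]
            cand_keys <- vapply(cands, function(t) fast_key(member_part, t), "")
            best <- order(cand_keys)[1]
            spec <- ssr_spec(c(list(s0), blocks), cands[[best]], order = 2)
            rows[[length(rows) + 1L]] <- list(
              k = k, partition = partition_enc, pattern = pat,
              key = cand_keys[best], spec = spec
            )
          }
        }
      }
    }
  }
  out <- tibble::tibble(
    id = sprintf("ssr2_%04d", seq_along(rows)),
    k = vapply(rows, `[[`, 1L, "k"),
    partition = vapply(rows, `[[`, "", "partition"),
    pattern = vapply(rows, `[[`, "", "pattern"),
    key = vapply(rows, `[[`, "", "key"),
    spec = lapply(rows, `[[`, "spec")
  )
  out$fn <- lapply(out$spec, as_reduction)
  out
}
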