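# Exact non-negative integer arithmetic on base-1e4 limb vectors
# (little-endian numerics). Counting restricted SSRs at order 3 and 4
# involves Stirling numbers far beyond 2^53, so the counting layer works on
# these exact integers throughout and only converts to doubles for display.

BIG_BASE <- 1e4

big_norm <- function(x) {
  x <- as.numeric(x)
  i <- 1L
  while (i <= length(x)) {
    if (x[i] >= BIG_BASE) {
      carry <- floor(x[i] / BIG_BASE)
      x[i] <- x[i] - carry * BIG_BASE
      if (i == length(x)) x <- c(x, 0)
      x[i + 1L] <- x[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_from_num <- function(n) {
  stopifnot(n >= 0, n == floor(n), n < 2^53)
  if (n == 0) return(0)
  limbs <- numeric(0)
  while (n > 0) {
    limbs <- c(limbs, n %% BIG_BASE)
    n <- floor(n / BIG_BASE)
  }
  limbs
}

big_from_string <- function(s) {
  s <- gsub("[ ,_]", "", s)
  stopifnot(grepl("^[0-9]+$", s))
  s <- sub("^0+(?=.)", "", s, perl = TRUE)
  n <- nchar(s)
  ends <- seq(n, 1, by = -4) # chunk ends, least significant first
  limbs <- vapply(ends, function(i) as.numeric(substr(s, max(1, i - 3), i)), 0)
  big_norm(limbs)
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- (i - 1L) + seq_along(b)
    out[idx] <- out[idx] + a[i] * b
  }
  # partial sums stay far below 2^53: limbs < 1e4, products < 1e8 each,
  # and fewer than 1e5 limbs are ever accumulated
  big_norm(out)
}

big_to_string <- function(x) {
  n <- length(x)
  parts <- vapply(rev(x), function(d) formatC(d, width = 4, flag = "0", format = "d"), "")
  parts[1] <- sub("^0+(?=.)", "", parts[1], perl = TRUE)
  paste0(parts, collapse = "")
}

#' Exact big integers
#'
#' A minimal arbitrary-precision non-negative integer type backing the
#' restricted-SSR counting formulas, which exceed double precision from
#' order 3 upward. Supports `+`, `*`, `^` (non-negative integer exponent),
#' comparisons, `as.character()`, `as.numeric()` and [bigint_signif()].
#'
#' @param x A non-negative integer-valued number, a decimal string, or a
#'   `bigint`.
#' @return An object of class `bigint`.
#' @examples
#' bigint(5)^16
#' as.character(stirling2(32, 4))
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  limbs <- if (is.character(x)) big_from_string(x) else big_from_num(x)
  structure(list(limbs = limbs), class = "bigint")
}

#' @export
as.character.bigint <- function(x, ...) big_to_string(x$limbs)

#' @export
as.double.bigint <- function(x, ...) {
  sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1))
}

#' @export
format.bigint <- function(x, ...) big_to_string(x$limbs)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", big_to_string(x$limbs), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.bigint <- function(e1, e2) {
  if (.Generic %in% c("+", "*", "^", "==", "!=", "<", ">", "<=", ">=")) {
    a <- bigint(e1)
    if (.Generic == "^") {
      k <- as.numeric(e2)
      stopifnot(k >= 0, k == floor(k))
      out <- bigint(1)
      base <- a
      while (k > 0) {
        if (k %% 2 == 1) out <- structure(list(limbs = big_mul(out$limbs, base$limbs)), class = "bigint")
        base <- structure(list(limbs = big_mul(base$limbs, base$limbs)), class = "bigint")
        k <- k %/% 2
      }
      return(out)
    }
    b <- bigint(e2)
    if (.Generic == "+") {
      return(structure(list(limbs = big_add(a$limbs, b$limbs)), class = "bigint"))
    }
    if (.Generic == "*") {
      return(structure(list(limbs = big_mul(a$limbs, b$limbs)), class = "bigint"))
    }
    cmp <- big_compare(a$limbs, b$limbs)
    return(switch(.Generic,
      "==" = cmp == 0L, "!=" = cmp != 0L,
      "<" = cmp < 0L, ">" = cmp > 0L,
      "<=" = cmp <= 0L, ">=" = cmp >= 0L))
  }
  stop("operation '", .Generic, "' not supported for bigint")
}

big_compare <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

#' Scientific notation for big integers
#'
#' Rounds a [bigint] to `digits` significant figures and formats it as
#' `m.me+XX`, e.g. `"2.9e+21"`.
#'
#' @param x A [bigint] (or anything [bigint()] accepts).
#' @param digits Significant digits (default 2).
#' @return A string.
#' @export
bigint_signif <- function(x, digits = 2) {
  s <- as.character(bigint(x))
  expo <- nchar(s) - 1L
  lead <- as.numeric(paste0(substr(s, 1, 1), ".", substr(s, 2, min(nchar(s), 16))))
  m <- signif(lead, digits)
  if (m >= 10) {
    m <- m / 10
    expo <- expo + 1L
  }
  sprintf("%se+%02d", format(m, nsmall = 0), expo)
}

# Stirling numbers of the second kind, exact, via the additive recurrence
# S(n,k) = k*S(n-1,k) + S(n-1,k-1); division-free so it stays exact on limb
# vectors. Returns a single bigint.

#' Stirling numbers of the second kind (exact)
#'
#' The number of ways to partition `n` labelled items into `k` non-empty
#' unlabelled blocks, computed in exact arbitrary-precision arithmetic.
#'
#' @param n,k Non-negative integers.
#' @return A [bigint].
#' @examples
#' as.numeric(stirling2(6, 2)) # 31
#' @export
stirling2 <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(bigint(0))
  if (n == 0) return(bigint(if (k == 0) 1 else 0))
  if (k == 0) return(bigint(0))
  # row-by-row DP over k' = 0..k
  prev <- c(list(big_from_num(1)), rep(list(big_from_num(0)), k))
  for (nn in seq_len(n)) {
    cur <- vector("list", k + 1L)
    cur[[1]] <- big_from_num(if (nn == 0) 1 else 0)
    for (kk in seq_len(k)) {
      cur[[kk + 1L]] <- big_add(big_mul(big_from_num(kk), prev[[kk + 1L]]), prev[[kk]])
    }
    prev <- cur
  }
  structure(list(limbs = prev[[k + 1L]]), class = "bigint")
}

# exact binomial coefficients via Pascal's triangle (additions only)
big_choose <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(bigint(0))
  k <- min(k, n - k)
  row <- list(big_from_num(1))
  for (nn in seq_len(n)) {
    newrow <- vector("list", min(nn, k) + 1L)
    newrow[[1]] <- big_from_num(1)
    for (j in seq_len(length(newrow) - 1L)) {
      above <- if (j + 1L <= length(row)) row[[j + 1L]] else big_from_num(0)
      newrow[[j + 1L]] <- big_add(row[[j]], above)
    }
    row <- newrow
  }
  structure(list(limbs = row[[k + 1L]]), class = "bigint")
}
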