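# Core representation of an order-l streaming sequence reduction (SSR):
# a total map g from all 4^l l-mers over {A,C,G,T} to {A,C,G,T, epsilon}.
# Internally epsilon is the empty string ""; on disk it is written "-".

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a reduction function
#'
#' A reduction function of order `l` is a total map `g` from every `l`-mer
#' over `{A, C, G, T}` to a single nucleotide or the empty output
#' (written `"-"` on disk, `""` in R). Sliding `g` over a sequence and
#' concatenating its outputs after the copied `l - 1` prefix characters
#' defines a streaming sequence reduction (SSR); homopolymer compression is
#' the order-2 special case that deletes the second letter of every
#' equal-letter dinucleotide.
#'
#' @param table Named character vector (or a data frame with columns
#'   `lmer`, `output`) mapping every `l`-mer to one of `"A"`, `"C"`, `"G"`,
#'   `"T"`, `""` or `"-"` (the last two both denote the empty output).
#' @param name Optional display name carried along in printing and reports.
#'
#' @return An object of class `reduction`: a named character vector of
#'   length `4^l` in lexicographic `l`-mer order, with attributes `order`
#'   and `name`.
#' @examples
#' hpc <- reduction_hpc()
#' apply_reduction(hpc, "AAAGGTTA")$seq
#' @export
reduction <- function(table, name = NULL) {
  if (is.data.frame(table)) {
    if (!all(c("lmer", "output") %in% names(table))) {
      stop("a reduction table data frame needs columns 'lmer' and 'output'")
    }
    tab <- as.character(table$output)
    names(tab) <- toupper(as.character(table$lmer))
    table <- tab
  }
  if (is.null(names(table))) stop("reduction table must be named by l-mer")
  names(table) <- toupper(names(table))
  table[table == "-"] <- ""
  lens <- unique(nchar(names(table)))
  if (length(lens) != 1L) stop("all l-mers must have the same length")
  l <- lens
  if (l < 1L) stop("order must be >= 1")
  keys <- all_lmers(l)
  dup <- names(table)[duplicated(names(table))]
  if (length(dup)) stop("duplicate l-mer(s) in table: ", toString(unique(dup)))
  missing <- setdiff(keys, names(table))
  if (length(missing)) {
    stop("reduction table is missing ", length(missing), " l-mer(s): ",
         toString(utils::head(missing, 5)))
  }
  extra <- setdiff(names(table), keys)
  if (length(extra)) stop("invalid l-mer(s) in table: ", toString(utils::head(extra, 5)))
  bad <- !(table %in% c(DNA_BASES, ""))
  if (any(bad)) {
    stop("invalid output symbol(s) for ", toString(names(table)[bad][seq_len(min(5, sum(bad)))]),
         " (allowed: A, C, G, T, '-')")
  }
  tab <- table[keys]
  structure(tab, order = as.integer(l), name = name, class = "reduction")
}

#' All l-mers over the DNA alphabet, lexicographically ordered
#'
#' @param l Word length (`l >= 1`).
#' @return Character vector of length `4^l`.
#' @export
all_lmers <- function(l) {
  stopifnot(l >= 1)
  grids <- rev(rep(list(DNA_BASES), l))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(g)))
}

#' @export
print.reduction <- function(x, ...) {
  l <- attr(x, "order")
  nm <- attr(x, "name")
  eps <- sum(x == "")
  cat("<reduction> order ", l, if (!is.null(nm)) paste0(" '", nm, "'"), "\n", sep = "")
  cat("  ", length(x), " l-mers; ", eps, " map to the empty output\n", sep = "")
  shown <- utils::head(x, 8)
  cat("  ", paste0(names(shown), "->", ifelse(shown == "", "-", shown), collapse = " "),
      if (length(x) > 8) " ...", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.reduction <- function(x, ...) {
  data.frame(lmer = names(x), output = ifelse(unclass(x) == "", "-", unclass(x)),
             stringsAsFactors = FALSE)
}

#' Tidy a reduction into a tibble
#'
#' @param x A `reduction`.
#' @param ... Unused.
#' @return A tibble with columns `lmer` and `output` (`"-"` denotes the
#'   empty output).
#' @export
tidy.reduction <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Order of a reduction
#'
#' @param f A `reduction`.
#' @return The window length `l`.
#' @export
reduction_order <- function(f) {
  stopifnot(inherits(f, "reduction"))
  attr(f, "order")
}

#' Canonical serialization of a reduction table
#'
#' Concatenates the outputs in lexicographic `l`-mer order, writing the
#' empty output as `"-"`. Two reductions are the same function iff their
#' serializations are equal; the enumeration of restricted SSRs uses this
#' string to pick the class representative and to assign stable ids.
#'
#' @param f A `reduction`.
#' @return A single string of length `4^l`.
#' @export
reduction_key <- function(f) {
  stopifnot(inherits(f, "reduction"))
  paste0(ifelse(unclass(f) == "", "-", unclass(f)), collapse = "")
}

# ---- reverse complement -----------------------------------------------------

#' Reverse complement of DNA strings
#'
#' Vectorized. Lowercase input is uppercased first. Characters outside
#' `{A, C, G, T}` are rejected when `strict = TRUE` (the default); with
#' `strict = FALSE` they are passed through unchanged (still reversed in
#' place), which keeps landmarks such as `N` runs visible.
#'
#' @param s Character vector of DNA strings.
#' @param strict Reject non-ACGT characters?
#' @return Character vector of the same length.
#' @examples
#' revcomp("TAAGTTGA") # "TCAACTTA"
#' @export
revcomp <- function(s, strict = TRUE) {
  s <- toupper(as.character(s))
  if (strict) {
    bad <- stringr::str_detect(s, "[^ACGT]")
    if (any(bad, na.rm = TRUE)) {
      off <- stringr::str_extract(s[which(bad)[1]], "[^ACGT]")
      stop("cannot reverse-complement character '", off,
           "': no defined complement (use strict = FALSE to pass through)")
    }
  }
  stringi::stri_reverse(chartr("ACGTacgt", "TGCATGCA", s))
}

#' Are two output symbols Watson-Crick complements?
#'
#' `TRUE` iff `{x, y}` is `{A, T}` or `{C, G}`. The empty output pairs with
#' nothing, so any comparison involving it is `FALSE`. Vectorized.
#'
#' @param x,y Symbols in `{A, C, G, T, "", "-"}`.
#' @return Logical vector.
#' @export
iscomp <- function(x, y) {
  x <- ifelse(x == "-", "", x)
  y <- ifelse(y == "-", "", y)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- x %in% DNA_BASES & y %in% DNA_BASES & unname(comp[x]) == y
  out & !is.na(out)
}

# ---- applying a reduction ---------------------------------------------------

# byte-level encoding: A,C,G,T -> 0..3, anything else NA
.base_codes <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1L] <- 0L; v[utf8ToInt("a") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L; v[utf8ToInt("c") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L; v[utf8ToInt("g") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L; v[utf8ToInt("t") + 1L] <- 3L
  v
})

# reduction table as a length-4^l integer vector of output bytes (0 = epsilon),
# indexed by base-4 window code + 1
.table_bytes <- function(f) {
  out <- unclass(f)
  b <- integer(length(out))
  for (base in DNA_BASES) b[out == base] <- utf8ToInt(base)
  unname(b)
}

#' Apply a reduction to a DNA sequence
#'
#' Implements the streaming transformation: the first `l - 1` characters are
#' copied verbatim, then `g` is applied to every length-`l` window from left
#' to right and its outputs are concatenated, with empty outputs dropped.
#' Sequences shorter than `l` are returned unchanged.
#'
#' Each emitted character is anchored to a 0-based position of the original
#' sequence: copied prefix characters to their own index, window outputs to
#' the index of the window's last character. The anchors form the
#' [position_map] used for coordinate lift-over.
#'
#' Characters outside `{A, C, G, T}` (after uppercasing) act as context
#' breaks: every window containing one emits nothing, and the offending
#' character itself is emitted verbatim exactly once, anchored to its own
#' position.
#'
#' @param f A [reduction].
#' @param s A single DNA string.
#' @return A list with elements `seq` (the reduced string) and `posmap`
#'   (a [position_map]).
#' @examples
#' apply_reduction(reduction_hpc(), "AAAGGTTA")
#' @export
apply_reduction <- function(f, s) {
  stopifnot(inherits(f, "reduction"), is.character(s), length(s) == 1L)
  l <- attr(f, "order")
  s <- toupper(s)
  n <- nchar(s)
  if (n < l) {
    return(list(seq = s, posmap = position_map(seq_len(n) - 1L, n)))
  }
  raw_s <- charToRaw(s)
  a <- .base_codes[as.integer(raw_s) + 1L]
  nw <- n - l + 1L
  # base-4 rolling code of each window; NA where any position is non-ACGT
  code <- integer(nw)
  na_win <- logical(nw)
  for (off in 0:(l - 1L)) {
    piece <- a[(1L + off):(nw + off)]
    na_win <- na_win | is.na(piece)
    piece[is.na(piece)] <- 0L
    code <- code * 4L + piece
  }
  tb <- .table_bytes(f)
  out_byte <- tb[code + 1L]
  out_byte[na_win] <- 0L
  # a non-ACGT character at the end of a window is emitted verbatim once
  last_idx <- l:n
  bad_last <- is.na(a[last_idx])
  out_byte[bad_last] <- as.integer(raw_s[last_idx[bad_last]])
  keep <- out_byte != 0L
  emitted <- rawToChar(as.raw(out_byte[keep]))
  prefix <- substr(s, 1L, l - 1L)
  anchors <- c(seq_len(l - 1L) - 1L, (which(keep) + l - 1L) - 1L)
  list(seq = paste0(prefix, emitted),
       posmap = position_map(anchors, n))
}

#' Reduce many sequences at once
#'
#' Applies a reduction to each element of a character vector, returning a
#' tibble. Quality strings, when given, are subset to the emitted positions
#' so FASTQ records stay consistent through the reduction.
#'
#' @param f A [reduction].
#' @param seqs Character vector of sequences (names are carried through).
#' @param quals Optional character vector of per-base quality strings of
#'   matching lengths.
#' @return A tibble with columns `name`, `seq`, and if `quals` was given
#'   `qual`; the list-column `posmap` holds one [position_map] per input.
#' @export
reduce_seqs <- function(f, seqs, quals = NULL) {
  stopifnot(inherits(f, "reduction"))
  nm <- names(seqs)
  if (is.null(nm)) nm <- as.character(seq_along(seqs))
  red <- lapply(unname(seqs), function(s) apply_reduction(f, s))
  out <- tibble::tibble(
    name = nm,
    seq = vapply(red, `[[`, "", "seq"),
    posmap = lapply(red, `[[`, "posmap")
  )
  if (!is.null(quals)) {
    stopifnot(length(quals) == length(seqs))
    out$qual <- vapply(seq_along(red), function(i) {
      idx <- anchors(red[[i]]$posmap) + 1L
      if (!length(idx)) return("")
      paste0(strsplit(quals[[i]], "", fixed = TRUE)[[1]][idx], collapse = "")
    }, "")
    out <- out[, c("name", "seq", "qual", "posmap")]
  }
  out
}

# fast batch application to ALL strings encoded as an integer code matrix
# (rows = strings, cols = positions, values 0..3); returns character vector.
# Used by the bounded RC-insensitivity verifier and property tests.
reduce_code_matrix <- function(f, m) {
  l <- attr(f, "order")
  n <- ncol(m)
  letters4 <- DNA_BASES
  if (n < l) {
    cols <- lapply(seq_len(n), function(j) letters4[m[, j] + 1L])
    return(do.call(paste0, cols))
  }
  out_sym <- unclass(f) # "" for epsilon: paste0 drops it naturally
  pieces <- lapply(seq_len(l - 1L), function(j) letters4[m[, j] + 1L])
  for (w in 1:(n - l + 1L)) {
    code <- m[, w]
    for (off in 1:(l - 1L)) code <- code * 4L + m[, w + off]
    pieces[[length(pieces) + 1L]] <- unname(out_sym[code + 1L])
  }
  do.call(paste0, pieces)
}

# integer code matrix of all 4^n strings of length n
all_code_matrix <- function(n) {
  g <- do.call(expand.grid, rep(list(0:3), n))
  m <- as.matrix(g[, rev(seq_len(n)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

codes_to_strings <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) DNA_BASES[m[, j] + 1L]))
}

# ---- reverse-complement properties -----------------------------------------

#' Test whether a reduction is RC-core-insensitive
#'
#' A reduction is reverse-complement-core-insensitive when its window
#' function sends every reverse-complement pair of `l`-mers to complementary
#' nucleotides, or both to the empty output; an `l`-mer equal to its own
#' reverse complement must map to the empty output (a single nucleotide
#' cannot be its own reverse complement).
#'
#' @param f A [reduction].
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_rc_core_insensitive(reduction_hpc())      # FALSE
#' is_rc_core_insensitive(reduction_example())  # TRUE
#' @export
is_rc_core_insensitive <- function(f) {
  stopifnot(inherits(f, "reduction"))
  keys <- names(f)
  rc <- revcomp(keys)
  gx <- unclass(f)[keys]
  gy <- unclass(f)[rc]
  both_eps <- gx == "" & gy == ""
  comp <- iscomp(gx, gy)
  all(ifelse(keys == rc, gx == "", both_eps | comp))
}

#' Bounded verifier for RC-insensitivity
#'
#' A reduction `f` is RC-insensitive when `f(RC(x)) == RC(f(x))` for every
#' string `x`. That quantifies over all strings, so this function checks the
#' identity exhaustively for every string of length 1 to `max_len` — a
#' bounded verifier, not a proof. Homopolymer compression passes at any
#' bound; RC-core-insensitive reductions generally fail at the copied
#' prefix.
#'
#' @param f A [reduction].
#' @param max_len Largest string length checked exhaustively (default 8).
#' @return `TRUE` if no counterexample up to `max_len`, else `FALSE`.
#' @export
is_rc_insensitive <- function(f, max_len = 8) {
  stopifnot(inherits(f, "reduction"), max_len >= attr(f, "order"))
  for (n in seq_len(max_len)) {
    m <- all_code_matrix(n)
    fx <- reduce_code_matrix(f, m)
    # RC at code level: reverse columns, complement = 3 - code
    mrc <- 3L - m[, rev(seq_len(n)), drop = FALSE]
    frc <- reduce_code_matrix(f, mrc)
    if (!identical(frc, revcomp(fx))) return(FALSE)
  }
  TRUE
}
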