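# Position maps record, for every character of a reduced sequence, the
# 0-based index of the original character it derives from. Anchors are
# strictly increasing, so interval lift-over in either direction is a
# binary search. All intervals are 0-based half-open.

#' Construct a position map
#'
#' @param anchors Strictly increasing integer vector; `anchors[i]` is the
#'   0-based original index that produced reduced position `i - 1`.
#' @param original_length Length of the original sequence.
#' @return An object of class `position_map`.
#' @export
position_map <- function(anchors, original_length) {
  anchors <- as.integer(anchors)
  original_length <- as.integer(original_length)
  if (length(anchors) && (anchors[1] < 0L || anchors[length(anchors)] >= original_length)) {
    stop("anchors must lie in [0, original_length)")
  }
  if (is.unsorted(anchors, strictly = TRUE)) stop("anchors must be strictly increasing")
  structure(list(anchors = anchors, original_length = original_length),
            class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat("<position_map> ", length(x$anchors), " reduced positions over ",
      x$original_length, " original\n", sep = "")
  invisible(x)
}

#' Anchors and lengths of a position map
#'
#' @param pm A [position_map].
#' @return `anchors()`: the integer anchor vector; `reduced_length()`: the
#'   number of reduced positions; `original_length()`: the original
#'   sequence length.
#' @export
anchors <- function(pm) pm$anchors

#' @rdname anchors
#' @export
reduced_length <- function(pm) length(pm$anchors)

#' @rdname anchors
#' @export
original_length <- function(pm) pm$original_length

#' Lift intervals between original and reduced coordinates
#'
#' `lift_to_reduced()` maps 0-based half-open intervals on the original
#' sequence onto the reduced sequence: the new start is the first reduced
#' position anchored at or past `start`, the new end is one past the last
#' reduced position anchored before `end`. An interval covering only
#' deleted positions comes back empty (`start == end`). This rounding keeps
#' the lifted interval inside the image of the original one, which is the
#' conservative direction for the overlap-based correctness test.
#'
#' `lift_to_original()` maps reduced intervals back: `start` becomes its
#' anchor, `end` becomes the anchor of `end - 1` plus one. Composing
#' `lift_to_reduced(lift_to_original(iv))` is the identity on reduced
#' intervals. Strand and any extra columns pass through untouched.
#'
#' @param intervals Data frame with columns `start`, `end` (0-based
#'   half-open); other columns are preserved.
#' @param pm A [position_map].
#' @return A tibble shaped like the input with translated `start`, `end`.
#' @examples
#' pm <- apply_reduction(reduction_hpc(), "AAAGGTTA")$posmap
#' lift_to_reduced(data.frame(start = 2, end = 8), pm) # [1, 4)
#' @export
lift_to_reduced <- function(intervals, pm) {
  stopifnot(inherits(pm, "position_map"))
  iv <- tibble::as_tibble(intervals)
  check_intervals(iv, pm$original_length)
  a <- pm$anchors
  # findInterval(q, a) counts anchors <= q; with integer anchors,
  # anchors < start  <=>  anchors <= start - 1
  s2 <- findInterval(iv$start - 1L, a)
  e2 <- findInterval(iv$end - 1L, a)
  iv$start <- s2
  iv$end <- pmax(e2, s2)
  iv
}

#' @rdname lift_to_reduced
#' @export
lift_to_original <- function(intervals, pm) {
  stopifnot(inherits(pm, "position_map"))
  iv <- tibble::as_tibble(intervals)
  check_intervals(iv, reduced_length(pm))
  a <- pm$anchors
  empty <- iv$end <= iv$start
  s <- iv$start
  e <- iv$end
  iv$start <- ifelse(empty, ifelse(s < length(a), a[s + 1L], pm$original_length), a[s + 1L])
  iv$end <- ifelse(empty, iv$start, a[e] + 1L)
  iv
}

check_intervals <- function(iv, space_len) {
  stopifnot(all(c("start", "end") %in% names(iv)))
  if (any(iv$start < 0 | iv$end < iv$start)) stop("intervals must satisfy 0 <= start <= end")
  if (any(iv$end > space_len)) stop("interval out of range: end beyond ", space_len)
  invisible(iv)
}

# ---- PAF translation --------------------------------------------------------

#' Translate PAF records between coordinate spaces
#'
#' Rewrites the target start/end (and target length) of minimap2-style PAF
#' records using per-target position maps, in either direction. Read names,
#' strand and mapq are untouched. Records whose `tp` tag marks them as
#' secondary can be dropped with `primary_only = TRUE`; records lacking the
#' tag are treated as primary.
#'
#' @param paf A PAF tibble as returned by [read_paf()] or [synth_mappings()].
#' @param posmaps Named list of [position_map]s, one per target sequence.
#' @param direction `"to_original"` (reduced PAF onto original coordinates)
#'   or `"to_reduced"`.
#' @param primary_only Drop secondary alignments first?
#' @return The translated PAF tibble.
#' @export
translate_paf <- function(paf, posmaps,
                          direction = c("to_original", "to_reduced"),
                          primary_only = FALSE) {
  direction <- match.arg(direction)
  paf <- tibble::as_tibble(paf)
  if (primary_only) paf <- dplyr::filter(paf, is.na(.data$tp) | .data$tp == "P")
  if (!nrow(paf)) return(paf)
  unknown <- setdiff(unique(paf$tname), names(posmaps))
  if (length(unknown)) stop("no position map for target(s): ", toString(unknown))
  lift <- if (direction == "to_original") lift_to_original else lift_to_reduced
  new_len <- function(pm) if (direction == "to_original") original_length(pm) else reduced_length(pm)
  parts <- lapply(split(paf, paf$tname), function(chunk) {
    pm <- posmaps[[chunk$tname[1]]]
    iv <- lift(tibble::tibble(start = chunk$tstart, end = chunk$tend), pm)
    chunk$tstart <- iv$start
    chunk$tend <- iv$end
    chunk$tlen <- new_len(pm)
    chunk
  })
  dplyr::arrange(dplyr::bind_rows(parts), .data$qname)
}
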