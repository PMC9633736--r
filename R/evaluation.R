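# Mapping evaluation: the mapeval-style placement-correctness criterion,
# cumulative mapq-threshold curves (fraction of reads mapped, mapping
# error rate), the respective-threshold rule against a reference point,
# and the three top-20 selection criteria whose union defines the
# mapping-friendly sequence reductions.

#' Placement correctness of mapped reads
#'
#' A read is correctly placed when its mapped target equals the truth
#' target and the intersection of its mapped interval with its true
#' interval of origin is at least 10% of the union of both intervals.
#' Both intervals must be in the same coordinate space.
#'
#' @param mappings Tibble with columns `qname`, `tname`, `tstart`, `tend`.
#' @param truths Tibble with columns `qname`, `tname`, `tstart`, `tend`
#'   (the simulated origin; unique `qname`s).
#' @param min_ratio Intersection-over-union cutoff (default 0.10).
#' @return Logical vector along the rows of `mappings`.
#' @export
is_correct <- function(mappings, truths, min_ratio = 0.10) {
  m <- tibble::as_tibble(mappings)
  t <- tibble::as_tibble(truths)
  if (anyDuplicated(t$qname)) stop("truth read names must be unique")
  idx <- match(m$qname, t$qname)
  if (anyNA(idx)) {
    stop("mapping(s) for unknown read name(s): ",
         toString(utils::head(unique(m$qname[is.na(idx)]), 5)))
  }
  same <- m$tname == t$tname[idx]
  inter <- pmax(0, pmin(m$tend, t$tend[idx]) - pmax(m$tstart, t$tstart[idx]))
  union <- (m$tend - m$tstart) + (t$tend[idx] - t$tstart[idx]) - inter
  same & union > 0 & inter / union >= min_ratio
}

#' Mapping evaluation curve over mapq thresholds
#'
#' For each threshold `t` (descending from 60 to 0 by default), considers
#' the primary alignments with `mapq >= t`: `fraction_mapped` is their
#' count over the total number of simulated reads, and `error_rate` is the
#' fraction of them that fail the placement-correctness criterion. Reads
#' without any mapping (e.g. reads whose reduced form is empty) count in
#' the denominator of `fraction_mapped` and can never be mapped. When no
#' read is mapped at a threshold the error rate is reported as 0 and
#' flagged in the `no_mapped` column.
#'
#' @param mappings PAF tibble; secondary records (`tp == "S"`) are dropped,
#'   records lacking the tag count as primary. One primary record per read
#'   is expected; duplicated primaries keep the highest-mapq one.
#' @param truths Truth tibble (`qname`, `tname`, `tstart`, `tend`), one row
#'   per simulated read, in the same coordinate space as `mappings`.
#' @param thresholds Integer mapq thresholds, reported in the given
#'   (conventionally decreasing) order.
#' @return An `eval_curve` tibble with columns `threshold`, `n_mapped`,
#'   `fraction_mapped`, `n_errors`, `error_rate`, `no_mapped`; attribute
#'   `total_reads`.
#' @export
eval_curve <- function(mappings, truths, thresholds = seq(60, 0, by = -10)) {
  m <- tibble::as_tibble(mappings)
  t <- tibble::as_tibble(truths)
  if (anyDuplicated(t$qname)) stop("truth read names must be unique")
  if ("tp" %in% names(m)) m <- dplyr::filter(m, is.na(.data$tp) | .data$tp == "P")
  if (nrow(m)) {
    m <- m |>
      dplyr::arrange(.data$qname, dplyr::desc(.data$mapq)) |>
      dplyr::distinct(.data$qname, .keep_all = TRUE)
  }
  total <- nrow(t)
  correct <- if (nrow(m)) is_correct(m, t) else logical(0)
  out <- lapply(thresholds, function(th) {
    sel <- m$mapq >= th
    n_mapped <- sum(sel)
    n_err <- sum(!correct[sel])
    tibble::tibble(
      threshold = th,
      n_mapped = n_mapped,
      fraction_mapped = if (total) n_mapped / total else 0,
      n_errors = n_err,
      error_rate = if (n_mapped) n_err / n_mapped else 0,
      no_mapped = n_mapped == 0
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "total_reads") <- total
  class(out) <- c("eval_curve", class(out))
  out
}

#' @export
glance.eval_curve <- function(x, ...) {
  tibble::tibble(
    total_reads = attr(x, "total_reads"),
    n_thresholds = nrow(x),
    fraction_mapped_all = x$fraction_mapped[which.min(x$threshold)],
    error_rate_all = x$error_rate[which.min(x$threshold)]
  )
}

#' Plot an evaluation curve
#'
#' Error rate against fraction mapped, one point per mapq threshold,
#' mirroring the standard presentation of mapping benchmarks (top-left
#' point = most stringent threshold).
#'
#' @param object An `eval_curve` (or a named list of them).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_mapped, y = .data$error_rate)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of reads mapped",
                  y = "mapping error rate",
                  title = "mapq-threshold evaluation curve") +
    ggplot2::theme_minimal()
}

curve_at <- function(curve, th) {
  i <- match(th, curve$threshold)
  if (is.na(i)) stop("curve has no point at threshold ", th)
  curve[i, ]
}

#' Respective mapq threshold against a reference point
#'
#' Scans a curve evaluated at every threshold 0..60 and returns the
#' highest threshold at which the curve is strictly better than the
#' reference on both axes (fraction mapped strictly higher AND error rate
#' strictly lower). Reductions with no such threshold are discarded from
#' selection (`NA` returned). The reference point is conventionally the
#' homopolymer-compression curve at mapq 60.
#'
#' @param curve An [eval_curve()] over thresholds 0..60.
#' @param ref_fraction,ref_error Reference fraction mapped and error rate.
#' @return Integer threshold, or `NA` if the curve never dominates.
#' @export
respective_threshold <- function(curve, ref_fraction, ref_error) {
  ok <- curve$fraction_mapped > ref_fraction & curve$error_rate < ref_error
  if (!any(ok)) return(NA_integer_)
  max(curve$threshold[ok])
}

#' Percentage of thresholds better than a reference
#'
#' The number of thresholds `t` in 1..60 at which the curve has strictly
#' higher fraction mapped and strictly lower error rate than the
#' reference, divided by 60 (threshold 0 excluded so the denominator is
#' exactly the 60 printed thresholds).
#'
#' @inheritParams respective_threshold
#' @return A fraction in \[0, 1\].
#' @export
percent_better <- function(curve, ref_fraction, ref_error) {
  sel <- curve$threshold >= 1 & curve$threshold <= 60
  if (sum(sel) < 60) stop("percent_better needs the curve at every threshold 1..60")
  ok <- curve$fraction_mapped[sel] > ref_fraction & curve$error_rate[sel] < ref_error
  sum(ok) / 60
}

#' Select mapping-friendly sequence reductions
#'
#' Implements the three-way selection against the homopolymer-compression
#' reference at mapq 60: for each candidate curve the respective threshold
#' is found (candidates without one are discarded); then the 20 candidates
#' with the highest fraction mapped at their respective thresholds, the 20
#' with the lowest error rate at their respective thresholds, and the 20
#' with the highest percentage of thresholds better than the reference are
#' ranked; the union of the three lists is the MSR set. Ties break by
#' metric then candidate id, so the outcome is reproducible. Three
#' best-in-category candidates are flagged: highest fraction mapped at
#' threshold 0 (`best_fraction`, the MSR_F analogue), lowest error rate at
#' the respective threshold (`best_error`, MSR_E), and highest
#' percent-better (`best_percent`, MSR_P).
#'
#' @param curves Named list of [eval_curve()]s over thresholds 0..60, one
#'   per candidate reduction.
#' @param hpc_curve Reference curve; its mapq-60 point supplies
#'   `ref_fraction` and `ref_error`.
#' @param top_n List length for each criterion (default 20).
#' @return An object of class `msr_selection`: list with `metrics` (per
#'   candidate tibble), `top_fraction`, `top_error`, `top_percent`
#'   (ranked tibbles), `union` (character ids), `best` (named character
#'   vector), and `reference`.
#' @export
select_msrs <- function(curves, hpc_curve, top_n = 20) {
  stopifnot(is.list(curves), !is.null(names(curves)))
  ref <- curve_at(hpc_curve, 60)
  ref_fraction <- ref$fraction_mapped
  ref_error <- ref$error_rate
  metrics <- dplyr::bind_rows(lapply(names(curves), function(id) {
    cv <- curves[[id]]
    rt <- respective_threshold(cv, ref_fraction, ref_error)
    at_rt <- if (!is.na(rt)) curve_at(cv, rt) else NULL
    tibble::tibble(
      id = id,
      respective_threshold = rt,
      fraction_at_rt = if (is.null(at_rt)) NA_real_ else at_rt$fraction_mapped,
      error_at_rt = if (is.null(at_rt)) NA_real_ else at_rt$error_rate,
      fraction_at_0 = curve_at(cv, 0)$fraction_mapped,
      percent_better = percent_better(cv, ref_fraction, ref_error)
    )
  }))
  qualifying <- dplyr::filter(metrics, !is.na(.data$respective_threshold))
  top_fraction <- qualifying |>
    dplyr::arrange(dplyr::desc(.data$fraction_at_rt), .data$id) |>
    utils::head(top_n)
  top_error <- qualifying |>
    dplyr::arrange(.data$error_at_rt, .data$id) |>
    utils::head(top_n)
  top_percent <- qualifying |>
    dplyr::arrange(dplyr::desc(.data$percent_better), .data$id) |>
    utils::head(top_n)
  best <- c(
    best_fraction = if (nrow(qualifying)) {
      dplyr::arrange(qualifying, dplyr::desc(.data$fraction_at_0), .data$id)$id[1]
    } else NA_character_,
    best_error = if (nrow(top_error)) top_error$id[1] else NA_character_,
    best_percent = if (nrow(top_percent)) top_percent$id[1] else NA_character_
  )
  structure(list(
    metrics = metrics,
    top_fraction = top_fraction,
    top_error = top_error,
    top_percent = top_percent,
    union = sort(unique(c(top_fraction$id, top_error$id, top_percent$id))),
    best = best,
    reference = c(fraction = ref_fraction, error = ref_error)
  ), class = "msr_selection")
}

#' @export
print.msr_selection <- function(x, ...) {
  cat("<msr_selection> ", nrow(x$metrics), " candidates, ",
      sum(!is.na(x$metrics$respective_threshold)), " qualifying, union of top lists: ",
      length(x$union), "\n", sep = "")
  cat("  reference point: fraction ", signif(x$reference[["fraction"]], 3),
      ", error ", signif(x$reference[["error"]], 3), "\n", sep = "")
  cat("  best in category: ", paste(names(x$best), x$best, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy an MSR selection
#'
#' @param x An `msr_selection`.
#' @param ... Unused.
#' @return A tibble of per-candidate metrics with membership flags
#'   `in_top_fraction`, `in_top_error`, `in_top_percent`, `selected`.
#' @export
tidy.msr_selection <- function(x, ...) {
  x$metrics |>
    dplyr::mutate(
      in_top_fraction = .data$id %in% x$top_fraction$id,
      in_top_error = .data$id %in% x$top_error$id,
      in_top_percent = .data$id %in% x$top_percent$id,
      selected = .data$id %in% x$union
    )
}

#' @export
glance.msr_selection <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$metrics),
    n_qualifying = sum(!is.na(x$metrics$respective_threshold)),
    n_selected = length(x$union),
    ref_fraction = x$reference[["fraction"]],
    ref_error = x$reference[["error"]]
  )
}

#' @export
autoplot.msr_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$fraction_at_rt)),
                  ggplot2::aes(x = .data$fraction_at_rt, y = .data$error_at_rt,
                               colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = tibble::tibble(x = object$reference[["fraction"]],
                            y = object$reference[["error"]]),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "orange", size = 3,
      inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "fraction mapped at respective threshold",
                  y = "error rate at respective threshold",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Restrict truths to reads originating in repeat regions
#'
#' Keeps the reads whose simulated origin overlaps the given repeat
#' intervals by more than half the read length, enabling repeat-only
#' re-evaluation. Overlap is computed against the union of the repeat
#' intervals per target.
#'
#' @param truths Truth tibble (`qname`, `tname`, `tstart`, `tend`).
#' @param repeats BED tibble (`chrom`, `start`, `end`).
#' @param min_fraction Minimum overlap as a fraction of read length
#'   (strictly greater than; default 0.5).
#' @return The filtered truth tibble.
#' @export
repeat_read_filter <- function(truths, repeats, min_fraction = 0.5) {
  t <- tibble::as_tibble(truths)
  if (!nrow(repeats) || !nrow(t)) return(t[integer(0), ])
  reads <- GenomicRanges::GRanges(t$tname, IRanges::IRanges(t$tstart + 1L, t$tend))
  reps <- GenomicRanges::reduce(
    GenomicRanges::GRanges(repeats$chrom, IRanges::IRanges(repeats$start + 1L, repeats$end))
  )
  hits <- GenomicRanges::findOverlaps(reads, reps)
  ov <- GenomicRanges::pintersect(reads[S4Vectors::queryHits(hits)],
                                  reps[S4Vectors::subjectHits(hits)])
  ov_by_read <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
  total <- numeric(nrow(t))
  total[as.integer(names(ov_by_read))] <- ov_by_read
  keep <- total > min_fraction * (t$tend - t$tstart)
  t[keep, ]
}
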