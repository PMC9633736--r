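# File formats. Reduction tables travel as TSV (columns lmer, output; "-"
# for the empty output) or an equivalent JSON object; FASTA/FASTQ go
# through Biostrings; PAF and BED are plain tab-separated tables; position
# maps are stored run-length encoded.

#' Read and write reduction tables
#'
#' The TSV dialect has a header line `lmer\toutput` and one row per
#' `l`-mer, with `"-"` denoting the empty output; rows may appear in any
#' order, and the table must be total (every `l`-mer exactly once).
#' The JSON dialect is a single object mapping `l`-mers to outputs.
#' `write_reduction()` always writes rows in lexicographic order.
#'
#' @param path File path; a `.json` suffix selects the JSON dialect.
#' @param f A [reduction].
#' @return `read_reduction()`: a [reduction]. `write_reduction()`: `path`,
#'   invisibly.
#' @export
read_reduction <- function(path) {
  name <- sub("\\.(tsv|json)$", "", basename(path))
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(reduction(unlist(obj), name = name))
  }
  tab <- utils::read.delim(path, colClasses = "character")
  if (!all(c("lmer", "output") %in% names(tab))) {
    stop("reduction TSV needs columns 'lmer' and 'output' (got: ",
         toString(names(tab)), ")")
  }
  reduction(stats::setNames(tab$output, tab$lmer), name = name)
}

#' @rdname read_reduction
#' @export
write_reduction <- function(f, path) {
  stopifnot(inherits(f, "reduction"))
  df <- as.data.frame(f)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(stats::setNames(df$output, df$lmer)), path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Sequence file input and output
#'
#' Thin wrappers over Biostrings keeping everything in plain named
#' character vectors (FASTA) or tibbles with `name`, `seq`, `qual`
#' (FASTQ). FASTA output is wrapped at 80 columns.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences.
#' @param reads Tibble with columns `name`, `seq`, `qual`.
#' @return `read_fasta()`: named character vector. `read_fastq()`: tibble.
#'   Writers return `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    name = sub("\\s.*$", "", names(x)),
    seq = unname(toupper(as.character(x))),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' @rdname read_fasta
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("name", "seq", "qual") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$name), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

# ---- PAF --------------------------------------------------------------------

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")

#' Read and write PAF mapping records
#'
#' Standard 12 mandatory columns, 0-based half-open target coordinates.
#' The `tp:A:` tag, when present, is parsed into a `tp` column (`"P"`
#' primary, `"S"` secondary, `"I"` inversion); records without the tag get
#' `NA` and are treated as primary downstream. Other tags are dropped on
#' read and absent on write (except `tp`, which is re-emitted).
#'
#' @param path File path.
#' @param paf A PAF tibble.
#' @return `read_paf()`: a tibble with the 12 mandatory columns plus `tp`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(
      qname = character(0), qlen = integer(0), qstart = integer(0),
      qend = integer(0), strand = character(0), tname = character(0),
      tlen = integer(0), tstart = integer(0), tend = integer(0),
      nmatch = integer(0), alen = integer(0), mapq = integer(0),
      tp = character(0)
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 12L
  if (any(short)) stop("PAF line(s) with fewer than 12 fields: line ", which(short)[1])
  core <- t(vapply(fields, function(f) f[1:12], character(12)))
  out <- tibble::as_tibble(stats::setNames(as.data.frame(core, stringsAsFactors = FALSE), PAF_COLS))
  for (col in c("qlen", "qstart", "qend", "tlen", "tstart", "tend", "nmatch", "alen", "mapq")) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$tp <- vapply(fields, function(f) {
    tp <- grep("^tp:A:", f[-(1:12)], value = TRUE)
    if (length(tp)) sub("^tp:A:", "", tp[1]) else NA_character_
  }, "")
  out
}

#' @rdname read_paf
#' @export
write_paf <- function(paf, path) {
  paf <- tibble::as_tibble(paf)
  stopifnot(all(PAF_COLS %in% names(paf)))
  core <- do.call(paste, c(paf[PAF_COLS], sep = "\t"))
  if ("tp" %in% names(paf)) {
    tag <- ifelse(is.na(paf$tp), "", paste0("\ttp:A:", paf$tp))
    core <- paste0(core, tag)
  }
  writeLines(core, path)
  invisible(path)
}

# ---- BED --------------------------------------------------------------------

#' Read and write BED intervals
#'
#' BED 3+ with 0-based half-open coordinates; only the first three columns
#' are interpreted (`chrom`, `start`, `end`), extra columns are preserved
#' as `X4`, `X5`, ...
#'
#' @param path File path.
#' @param bed Tibble with columns `chrom`, `start`, `end`.
#' @return `read_bed()`: a tibble.
#' @export
read_bed <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    return(tibble::tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  n_fields <- max(utils::count.fields(path, sep = "\t"))
  tab <- utils::read.delim(path, header = FALSE, colClasses = c("character", "integer", "integer",
                                                                rep(NA, max(0, n_fields - 3))))
  names(tab)[1:3] <- c("chrom", "start", "end")
  tibble::as_tibble(tab)
}

#' @rdname read_bed
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- position maps ----------------------------------------------------------

#' Read and write per-target position maps
#'
#' Serializes a named list of [position_map]s as a run-length encoded TSV
#' sidecar (columns `target`, `reduced_start`, `original_start`, `length`,
#' `original_length`): each row covers a maximal run where reduced and
#' original positions advance in lockstep, so homopolymer-compressed
#' genomes stay compact.
#'
#' @param posmaps Named list of [position_map]s.
#' @param path File path.
#' @return `read_position_maps()`: named list of [position_map]s.
#' @export
write_position_maps <- function(posmaps, path) {
  stopifnot(is.list(posmaps), !is.null(names(posmaps)))
  rows <- lapply(names(posmaps), function(nm) {
    pm <- posmaps[[nm]]
    a <- anchors(pm)
    if (!length(a)) {
      return(tibble::tibble(target = nm, reduced_start = integer(0),
                            original_start = integer(0), length = integer(0),
                            original_length = original_length(pm)))
    }
    run_break <- c(TRUE, diff(a) != 1L)
    run_id <- cumsum(run_break)
    starts <- which(run_break)
    tibble::tibble(
      target = nm,
      reduced_start = starts - 1L,
      original_start = a[starts],
      length = as.integer(tabulate(run_id)),
      original_length = original_length(pm)
    )
  })
  utils::write.table(dplyr::bind_rows(rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_position_maps
#' @export
read_position_maps <- function(path) {
  tab <- utils::read.delim(path)
  out <- lapply(split(tab, tab$target), function(chunk) {
    chunk <- chunk[order(chunk$reduced_start), , drop = FALSE]
    a <- unlist(lapply(seq_len(nrow(chunk)), function(i) {
      chunk$original_start[i] + seq_len(chunk$length[i]) - 1L
    }))
    position_map(as.integer(a), chunk$original_length[1])
  })
  out[unique(tab$target)]
}
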