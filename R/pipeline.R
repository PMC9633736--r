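# End-to-end pipeline: reduce reference and reads with each candidate
# reduction, obtain mappings in reduced space (external mapper template or
# the synthetic mapper), translate truth onto the reduced reference,
# evaluate, and select. Mirrors the shape reduce -> map -> translate ->
# evaluate -> select.

#' Pipeline configuration
#'
#' @param ssrs Character vector of reduction names/paths (see
#'   [get_reduction()]), or a named list of [reduction]s. Must include
#'   `"hpc"` (or a reduction named `hpc`), the selection reference.
#' @param sim A [sim_config()] describing the synthetic dataset, or `NULL`
#'   if `genome_fa`/`reads_fq` are given.
#' @param genome_fa,reads_fq Optional paths to an existing FASTA reference
#'   and FASTQ reads with truth-encoded names (used instead of `sim`).
#' @param mapper Optional external mapper command template with
#'   placeholders `{ref}`, `{reads}`, `{out}`; when `NULL`, mappings are
#'   synthesized with [synth_mappings()] using `wrong_rate` and
#'   `mapq_model`. The conventional template for a minimap2-style mapper
#'   is `"minimap2 -x map-ont -c {ref} {reads} > {out}"`.
#' @param wrong_rate,mapq_model Parameters of the synthetic mapper.
#' @param thresholds Mapq thresholds for the reported curves (the
#'   selection internally always uses 0..60).
#' @param outdir Run directory for all outputs.
#' @param seed Integer seed for the synthetic mapper.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ssrs = c("raw", "hpc", "example"),
                            sim = sim_config(),
                            genome_fa = NULL, reads_fq = NULL,
                            mapper = NULL,
                            wrong_rate = 0.05,
                            mapq_model = mapq_confidence(),
                            thresholds = 0:60,
                            outdir = tempfile("msr_run_"),
                            seed = 1) {
  if (!is.list(ssrs)) {
    ssrs <- stats::setNames(lapply(ssrs, get_reduction), ssrs)
  }
  if (is.null(names(ssrs)) || any(!nzchar(names(ssrs)))) {
    stop("ssrs must be named")
  }
  if (is.null(sim) && (is.null(genome_fa) || is.null(reads_fq))) {
    stop("either a sim config or genome_fa + reads_fq paths are required")
  }
  if (!is.null(genome_fa) && !file.exists(genome_fa)) stop("genome_fa not found: ", genome_fa)
  if (!is.null(reads_fq) && !file.exists(reads_fq)) stop("reads_fq not found: ", reads_fq)
  structure(as.list(environment()), class = "pipeline_config")
}

run_mapper_template <- function(template, ref, reads, out) {
  cmd <- stringr::str_replace_all(template, c(
    "\\{ref\\}" = shQuote(ref),
    "\\{reads\\}" = shQuote(reads),
    "\\{out\\}" = shQuote(out)
  ))
  status <- system(cmd)
  if (status != 0) stop("mapper command failed (exit ", status, "): ", cmd)
  invisible(out)
}

#' Run the full reduction-mapping-evaluation pipeline
#'
#' For every configured reduction: the reference and reads are reduced and
#' written to the run directory together with the reference position-map
#' sidecar; mappings in reduced coordinates come either from the external
#' mapper template or from the synthetic mapper; truth intervals are
#' lifted onto the reduced reference; the primary alignments are evaluated
#' into a mapq-threshold curve. Finally the selection procedure is run
#' against the homopolymer-compression curve, and curves, a selection
#' report and a JSON manifest are written. A failing mapper invocation is
#' recorded per reduction and the run continues.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `curves` (named
#'   list of [eval_curve()]s), `selection` ([select_msrs()] output or
#'   `NULL`), `errors` (named character), `outdir`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$genome_fa)) {
    genome <- read_fasta(cfg$genome_fa)
    reads <- read_fastq(cfg$reads_fq)
    truths <- parse_truth_names(reads$name)
  } else {
    gen <- generate_genome(cfg$sim)
    genome <- gen$genome
    sim <- simulate_reads(genome, cfg$sim)
    reads <- sim$reads
    truths <- sim$truths
    write_fasta(genome, file.path(cfg$outdir, "genome.fa"))
    write_bed(gen$repeats, file.path(cfg$outdir, "repeats.bed"))
  }
  curves <- list()
  errors <- character(0)
  files <- character(0)
  for (nm in names(cfg$ssrs)) {
    f <- cfg$ssrs[[nm]]
    ssr_dir <- file.path(cfg$outdir, nm)
    dir.create(ssr_dir, showWarnings = FALSE)
    red_ref <- reduce_seqs(f, genome)
    posmaps <- stats::setNames(red_ref$posmap, red_ref$name)
    ref_path <- file.path(ssr_dir, "reference.fa")
    write_fasta(stats::setNames(red_ref$seq, red_ref$name), ref_path)
    write_position_maps(posmaps, file.path(ssr_dir, "reference.posmap.tsv"))
    red_reads <- reduce_seqs(f, stats::setNames(reads$seq, reads$name), reads$qual)
    reads_path <- file.path(ssr_dir, "reads.fq")
    write_fastq(red_reads, reads_path)
    # truth intervals lifted onto the reduced reference, per target
    red_truths <- dplyr::bind_rows(lapply(split(truths, truths$tname), function(chunk) {
      pm <- posmaps[[chunk$tname[1]]]
      iv <- lift_to_reduced(tibble::tibble(start = chunk$tstart, end = chunk$tend), pm)
      chunk$tstart <- iv$start
      chunk$tend <- iv$end
      chunk
    }))
    red_truths <- red_truths[match(truths$qname, red_truths$qname), ]
    paf_path <- file.path(ssr_dir, "mappings.paf")
    paf <- tryCatch({
      if (!is.null(cfg$mapper)) {
        run_mapper_template(cfg$mapper, ref_path, reads_path, paf_path)
        read_paf(paf_path)
      } else {
        tlen <- stats::setNames(nchar(red_ref$seq), red_ref$name)
        mappable <- red_truths[nchar(red_reads$seq) > 0 & red_truths$tend > red_truths$tstart, ]
        p <- synth_mappings(mappable, tlen, wrong_rate = cfg$wrong_rate,
                            mapq_model = cfg$mapq_model, seed = cfg$seed)
        write_paf(p, paf_path)
        p
      }
    }, error = function(e) {
      errors[[nm]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(paf)) next
    paf <- dplyr::filter(paf, is.na(.data$tp) | .data$tp == "P")
    curve <- eval_curve(paf, red_truths, thresholds = cfg$thresholds)
    curves[[nm]] <- curve
    curve_path <- file.path(ssr_dir, "curve.tsv")
    utils::write.table(tibble::as_tibble(curve), curve_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, curve_path)
  }
  selection <- NULL
  if ("hpc" %in% names(curves) && all(0:60 %in% cfg$thresholds)) {
    selection <- select_msrs(curves, curves[["hpc"]])
    sel_path <- file.path(cfg$outdir, "selection.tsv")
    utils::write.table(tidy(selection), sel_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, sel_path)
  }
  manifest <- list(
    package = "msrtools",
    version = as.character(utils::packageVersion("msrtools")),
    seed = cfg$seed,
    wrong_rate = if (is.null(cfg$mapper)) cfg$wrong_rate else NULL,
    mapper = cfg$mapper,
    ssrs = names(cfg$ssrs),
    n_reads = nrow(reads),
    errors = as.list(errors)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  structure(list(curves = curves, selection = selection, errors = errors,
                 outdir = cfg$outdir, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$curves), " curve(s) in ", x$outdir, "\n", sep = "")
  if (length(x$errors)) {
    cat("  errors: ", paste(names(x$errors), x$errors, sep = ": ", collapse = "; "), "\n", sep = "")
  }
  if (!is.null(x$selection)) {
    cat("  selection union size: ", length(x$selection$union), "\n", sep = "")
  }
  invisible(x)
}
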