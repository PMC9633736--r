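# Seeded synthetic fixtures: a small genome with tunable homopolymer
# content and a diverged tandem-repeat cassette, nanopore-like reads with
# substitution and homopolymer expansion/contraction errors and their true
# origins encoded in the read names, and synthetic PAF mappings with a
# controlled wrong-placement rate. Everything is deterministic under the
# configured seed. The generator deliberately implements a minimal,
# parameterized error process rather than a trained sequencing error
# model: enough structure to exercise reduction, lift-over and evaluation,
# not a claim of read-level realism.

#' Simulation configuration
#'
#' Defaults describe a small two-chromosome genome (100 kb total) with
#' mild homopolymer enrichment and one diverged tandem-repeat array, read
#' lengths around 2 kb (roughly nanopore-scale, scaled down), a 1%
#' substitution rate and a 50% chance of a one-base expansion or
#' contraction per homopolymer run, with half the reads on the reverse
#' strand.
#'
#' @param genome_length Total genome length in bases.
#' @param n_chromosomes Number of chromosomes (length split evenly).
#' @param homopolymer_rate Probability that a base copies its predecessor
#'   instead of being drawn uniformly (0 = iid sequence).
#' @param repeat_unit_length,repeat_copies,repeat_divergence Tandem repeat
#'   cassette: unit length, number of copies inserted on chromosome 1, and
#'   per-copy substitution rate.
#' @param n_reads Number of simulated reads.
#' @param read_length_mean,read_length_sd,read_length_min Read length
#'   distribution (normal, truncated at the minimum).
#' @param substitution_rate Per-base substitution probability.
#' @param homopolymer_error_rate Probability that a homopolymer run of
#'   length >= 2 in a read is expanded or contracted by one base.
#' @param reverse_prob Probability a read comes from the reverse strand.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e5,
                       n_chromosomes = 2,
                       homopolymer_rate = 0.3,
                       repeat_unit_length = 200,
                       repeat_copies = 10,
                       repeat_divergence = 0.02,
                       n_reads = 2000,
                       read_length_mean = 2000,
                       read_length_sd = 500,
                       read_length_min = 200,
                       substitution_rate = 0.01,
                       homopolymer_error_rate = 0.5,
                       reverse_prob = 0.5,
                       seed = 42) {
  cfg <- as.list(environment())
  probs <- c(cfg$homopolymer_rate, cfg$repeat_divergence, cfg$substitution_rate,
             cfg$homopolymer_error_rate, cfg$reverse_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$genome_length > 0, cfg$n_chromosomes >= 1,
            cfg$n_reads >= 0, cfg$read_length_min > 0)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, homopolymer_rate = 0) {
  bases <- sample(DNA_BASES, n, replace = TRUE)
  if (homopolymer_rate > 0 && n > 1) {
    copy <- stats::runif(n - 1) < homopolymer_rate
    for (i in which(copy)) bases[i + 1L] <- bases[i]
  }
  paste0(bases, collapse = "")
}

mutate_bases <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  paste0(chars, collapse = "")
}

#' Generate a synthetic genome with repeats
#'
#' Chromosomes are homopolymer-enriched random DNA; a tandem array of
#' diverged copies of one repeat unit is inserted mid-way into the first
#' chromosome, and each copy's interval is reported as a BED row. All
#' randomness derives from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (named character vector) and `repeats`
#'   (BED tibble: `chrom`, `start`, `end`).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    chrom_len <- floor(cfg$genome_length / cfg$n_chromosomes)
    genome <- stats::setNames(
      vapply(seq_len(cfg$n_chromosomes),
             function(i) random_dna(chrom_len, cfg$homopolymer_rate), ""),
      paste0("chr", seq_len(cfg$n_chromosomes))
    )
    repeats <- tibble::tibble(chrom = character(0), start = integer(0), end = integer(0))
    if (cfg$repeat_copies > 0) {
      unit <- random_dna(cfg$repeat_unit_length)
      copies <- vapply(seq_len(cfg$repeat_copies),
                       function(i) mutate_bases(unit, cfg$repeat_divergence), "")
      cassette <- paste0(copies, collapse = "")
      insert_at <- floor(chrom_len / 2) # 0-based insertion point
      s <- genome[[1]]
      genome[[1]] <- paste0(substr(s, 1, insert_at), cassette,
                            substr(s, insert_at + 1, chrom_len))
      starts <- insert_at + (seq_len(cfg$repeat_copies) - 1L) * cfg$repeat_unit_length
      repeats <- tibble::tibble(
        chrom = names(genome)[1],
        start = as.integer(starts),
        end = as.integer(starts + cfg$repeat_unit_length)
      )
    }
    list(genome = genome, repeats = repeats)
  })
}

# expand/contract homopolymer runs of length >= 2, one base with prob p
jitter_homopolymers <- function(s, p) {
  if (p <= 0 || nchar(s) < 2) return(s)
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  eligible <- which(r$lengths >= 2)
  if (length(eligible)) {
    hit <- eligible[stats::runif(length(eligible)) < p]
    delta <- sample(c(-1L, 1L), length(hit), replace = TRUE)
    r$lengths[hit] <- pmax(1L, r$lengths[hit] + delta)
  }
  paste0(rep(r$values, r$lengths), collapse = "")
}

#' Simulate reads with encoded truth
#'
#' Draws origin intervals uniformly along the genome, reverse-complements
#' reads assigned to the reverse strand, then applies the error process
#' (per-run homopolymer length jitter followed by substitutions). Truth
#' always refers to the error-free origin interval on the forward
#' reference, and is encoded in each read name as
#' `id!target!start!end!strand` in addition to the returned tibble.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param cfg A [sim_config()].
#' @return A list with `reads` (tibble: `name`, `seq`, `qual`) and
#'   `truths` (tibble: `qname`, `tname`, `tstart`, `tend`, `strand`).
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    lens <- nchar(genome)
    n <- cfg$n_reads
    rl <- pmax(cfg$read_length_min,
               round(stats::rnorm(n, cfg$read_length_mean, cfg$read_length_sd)))
    rl <- pmin(rl, min(lens))
    chrom <- sample(names(genome), n, replace = TRUE, prob = lens)
    start <- vapply(seq_len(n), function(i) {
      sample.int(lens[[chrom[i]]] - rl[i] + 1L, 1L) - 1L
    }, 1L)
    strand <- ifelse(stats::runif(n) < cfg$reverse_prob, "-", "+")
    id <- sprintf("read%05d", seq_len(n))
    name <- paste(id, chrom, start, start + rl, strand, sep = "!")
    seqs <- vapply(seq_len(n), function(i) {
      s <- substr(genome[[chrom[i]]], start[i] + 1L, start[i] + rl[i])
      if (strand[i] == "-") s <- revcomp(s)
      mutate_bases(jitter_homopolymers(s, cfg$homopolymer_error_rate),
                   cfg$substitution_rate)
    }, "")
    reads <- tibble::tibble(
      name = name,
      seq = seqs,
      qual = vapply(nchar(seqs), function(k) strrep("I", k), "")
    )
    truths <- tibble::tibble(
      qname = name, tname = chrom,
      tstart = as.integer(start), tend = as.integer(start + rl),
      strand = strand
    )
    list(reads = reads, truths = truths)
  })
}

#' Decode truth intervals from read names
#'
#' Inverse of the `id!target!start!end!strand` naming convention of
#' [simulate_reads()].
#'
#' @param names Character vector of read names.
#' @return Truth tibble (`qname`, `tname`, `tstart`, `tend`, `strand`).
#' @export
parse_truth_names <- function(names) {
  parts <- stringr::str_split_fixed(names, stringr::fixed("!"), 5)
  if (any(parts[, 5] == "")) stop("read name(s) not in id!target!start!end!strand form")
  tibble::tibble(
    qname = names, tname = parts[, 2],
    tstart = as.integer(parts[, 3]), tend = as.integer(parts[, 4]),
    strand = parts[, 5]
  )
}

#' Synthesize PAF mappings with a controlled error rate
#'
#' Emits one primary PAF record per truth row. With probability
#' `wrong_rate` the record is displaced to a uniformly drawn locus of the
#' same length that does not overlap the true origin (rejection-sampled);
#' otherwise it reproduces the truth interval. Mapq values come from
#' `mapq_model`, a function of the per-read correctness flag. Everything
#' is deterministic under `seed`.
#'
#' @param truths Truth tibble (`qname`, `tname`, `tstart`, `tend`, and
#'   optionally `strand`).
#' @param target_lengths Named integer vector (or tibble `tname`, `tlen`)
#'   of target sequence lengths in the same coordinate space.
#' @param wrong_rate Probability of a wrong placement.
#' @param mapq_model Function `(wrong: logical) -> integer mapq vector`;
#'   see [mapq_uniform()] and [mapq_confidence()].
#' @param seed Integer seed.
#' @return A PAF tibble (12 mandatory columns plus `tp = "P"`).
#' @export
synth_mappings <- function(truths, target_lengths, wrong_rate = 0,
                           mapq_model = mapq_uniform(), seed = 1) {
  t <- tibble::as_tibble(truths)
  stopifnot(wrong_rate >= 0, wrong_rate <= 1)
  if (is.data.frame(target_lengths)) {
    target_lengths <- stats::setNames(target_lengths$tlen, target_lengths$tname)
  }
  missing <- setdiff(unique(t$tname), names(target_lengths))
  if (length(missing)) stop("no target length for: ", toString(missing))
  withr::with_seed(seed, {
    n <- nrow(t)
    wrong <- stats::runif(n) < wrong_rate
    tname <- t$tname
    tstart <- t$tstart
    tend <- t$tend
    len <- tend - tstart
    for (i in which(wrong)) {
      repeat {
        cand_t <- sample(names(target_lengths), 1L)
        room <- target_lengths[[cand_t]] - len[i]
        if (room < 0) next
        cand_s <- sample.int(room + 1L, 1L) - 1L
        overlaps <- cand_t == t$tname[i] &&
          cand_s < t$tend[i] && (cand_s + len[i]) > t$tstart[i]
        if (!overlaps) break
      }
      tname[i] <- cand_t
      tstart[i] <- cand_s
      tend[i] <- cand_s + len[i]
    }
    tibble::tibble(
      qname = t$qname,
      qlen = as.integer(len),
      qstart = 0L,
      qend = as.integer(len),
      strand = if ("strand" %in% names(t)) t$strand else "+",
      tname = tname,
      tlen = as.integer(unname(target_lengths[tname])),
      tstart = as.integer(tstart),
      tend = as.integer(tend),
      nmatch = as.integer(len),
      alen = as.integer(len),
      mapq = as.integer(mapq_model(wrong)),
      tp = "P"
    )
  })
}

#' Mapq models for synthetic mappings
#'
#' `mapq_uniform()` draws mapq uniformly from `values` regardless of
#' correctness, so placement errors are spread evenly across thresholds.
#' `mapq_confidence()` draws high mapq for correct placements and low mapq
#' for wrong ones, giving curves whose error concentrates at low
#' thresholds (the realistic aligner-like shape).
#'
#' @param values Candidate mapq values.
#' @param correct_values,wrong_values Candidate values per class.
#' @return A function `(wrong: logical) -> integer`.
#' @export
mapq_uniform <- function(values = 0:60) {
  force(values)
  function(wrong) sample(values, length(wrong), replace = TRUE)
}

#' @rdname mapq_uniform
#' @export
mapq_confidence <- function(correct_values = 40:60, wrong_values = 0:30) {
  force(correct_values); force(wrong_values)
  function(wrong) {
    out <- integer(length(wrong))
    out[!wrong] <- sample(correct_values, sum(!wrong), replace = TRUE)
    out[wrong] <- sample(wrong_values, sum(wrong), replace = TRUE)
    out
  }
}

#' Write a full simulated dataset to a directory
#'
#' Runs [generate_genome()] and [simulate_reads()] and writes
#' `genome.fa`, `repeats.bed`, `reads.fq` and `truth.tsv`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths.
#' @export
write_simulated_dataset <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(cfg)
  sim <- simulate_reads(gen$genome, cfg)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    repeats = file.path(outdir, "repeats.bed"),
    reads = file.path(outdir, "reads.fq"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_fasta(gen$genome, paths$genome)
  write_bed(gen$repeats, paths$repeats)
  write_fastq(sim$reads, paths$reads)
  utils::write.table(sim$truths, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
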