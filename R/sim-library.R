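#' Configuration for the small RNA read simulator
#'
#' Read counts are split across the three locus archetypes by
#' `class_weights` (default 65% hc-siRNA, 30% miRNA, 5% tasiRNA; at five
#' million reads this is roughly 3.25 M, 1.5 M and 250 k reads). Sequencing
#' errors are single-base substitutions applied to one read in
#' `1/error_rate` (default one mis-sequenced base per 10,000 reads).
#'
#' Misprocessing is modelled per read as a length deviation from the class's
#' canonical length (24 nt for hc-siRNA, 21 nt for miRNA and tasiRNA) and a
#' +/-1 nt shift of the leftmost coordinate:
#' `length_delta_probs` gives P(delta) for delta in -2..+2 and
#' `shift_probs` gives P(shift) for shift in -1..+1. Drawn lengths are
#' clamped to `length_range`.
#'
#' @param n_reads Number of reads to simulate.
#' @param class_weights Named fractions over `hc_siRNA`, `miRNA`, `tasiRNA`,
#'   summing to 1.
#' @param error_rate Per-read probability of one substituted base.
#' @param length_delta_probs Probabilities for length deviations -2..+2 nt.
#' @param shift_probs Probabilities for 5' shifts -1..+1 nt.
#' @param mirna_star_ratio miRNA:miRNA* abundance ratio (default 10:1).
#' @param length_range Allowed read lengths (nt); drawn lengths are clamped.
#' @param rng_seed Integer seed.
#' @return An object of class `sim_library_config`.
#' @export
sim_library_config <- function(n_reads,
                               class_weights = c(hc_siRNA = 0.65,
                                                 miRNA = 0.30,
                                                 tasiRNA = 0.05),
                               error_rate = 1e-4,
                               length_delta_probs = c(`-2` = 0.02, `-1` = 0.08,
                                                      `0` = 0.80,
                                                      `1` = 0.08, `2` = 0.02),
                               shift_probs = c(`-1` = 0.05, `0` = 0.90,
                                               `1` = 0.05),
                               mirna_star_ratio = 10,
                               length_range = c(20L, 25L),
                               rng_seed = 1L) {
  req <- c("hc_siRNA", "miRNA", "tasiRNA")
  if (!all(req %in% names(class_weights)))
    stop("class_weights must be named hc_siRNA, miRNA, tasiRNA")
  class_weights <- class_weights[req]
  if (abs(sum(class_weights) - 1) > 1e-12)
    stop("class_weights must sum to 1")
  if (error_rate < 0 || error_rate > 1)
    stop("error_rate must be in [0, 1]")
  stopifnot(n_reads >= 0, abs(sum(length_delta_probs) - 1) < 1e-9,
            abs(sum(shift_probs) - 1) < 1e-9, mirna_star_ratio > 0,
            length_range[1] <= length_range[2])
  structure(list(n_reads = as.integer(n_reads),
                 class_weights = class_weights,
                 error_rate = error_rate,
                 length_delta_probs = length_delta_probs,
                 shift_probs = shift_probs,
                 mirna_star_ratio = mirna_star_ratio,
                 length_range = as.integer(length_range),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_library_config")
}

CANONICAL_LENGTH <- c(hc_siRNA = 24L, miRNA = 21L, tasiRNA = 21L)
# mature miRNA register offset within the 125-nt hairpin locus (5' arm)
MIRNA_MATURE_OFFSET <- 20L

draw_delta <- function(n, probs) {
  as.integer(sample(as.integer(names(probs)), n, replace = TRUE, prob = probs))
}

#' Simulate a traceable small RNA-seq library
#'
#' Each read is drawn by (1) class according to `class_weights`, (2) locus
#' according to per-locus `abundance_weight` within the class, (3) a
#' class-specific position/strand/length model, then (4) with probability
#' `error_rate` one base is substituted at a uniform position.
#'
#' Positional models: hc-siRNA reads start uniformly within the locus on
#' either strand; miRNA loci emit plus-strand reads from the mature register
#' (offset 20 in the hairpin) or the miRNA* register (duplex partner with a
#' 2-nt 3' overhang) with abundance ratio `mirna_star_ratio`:1; tasiRNA loci
#' emit 21-nt phased registers from both strands anchored at the locus start
#' (minus-strand registers offset by the 2-nt overhang), with register
#' weights drawn once per locus.
#'
#' Read IDs encode `locus_id|reference|true_start|strand|serial` so the
#' truth is recoverable from the FASTQ alone; the truth table remains the
#' canonical record.
#'
#' @param genome A `sim_genome` or [Biostrings::DNAStringSet].
#' @param loci Locus data frame (as produced by [generate_genome()]);
#'   ignored when `genome` is a `sim_genome`.
#' @param config A [sim_library_config()].
#' @return A list of class `sim_library` with `reads` (data frame:
#'   `read_id`, `sequence`, `has_error`) and `truth` (data frame: `read_id`,
#'   `locus_id`, `class`, `true_reference`, `true_start`, `true_strand`,
#'   `has_error`).
#' @export
simulate_library <- function(genome, loci = NULL, config) {
  if (inherits(genome, "sim_genome")) {
    loci <- genome$loci
    genome <- genome$genome
  }
  stopifnot(inherits(config, "sim_library_config"))
  n <- config$n_reads
  empty <- function() {
    truth <- data.frame(read_id = character(0), locus_id = character(0),
                        class = character(0), true_reference = character(0),
                        true_start = integer(0), true_strand = character(0),
                        has_error = logical(0))
    reads <- data.frame(read_id = character(0), sequence = character(0),
                        has_error = logical(0))
    structure(list(reads = reads, truth = truth), class = "sim_library")
  }
  if (n == 0L) return(empty())
  if (is.null(loci) || nrow(loci) == 0L)
    stop("cannot simulate reads from an empty locus table")
  for (cl in names(config$class_weights))
    if (config$class_weights[[cl]] > 0 && !any(loci$class == cl))
      stop("class ", cl, " has positive weight but no loci")

  set.seed(config$rng_seed)
  ref_seq <- as.character(genome)
  ref_len <- stats::setNames(nchar(ref_seq), names(genome))

  cls <- sample(names(config$class_weights), n, replace = TRUE,
                prob = config$class_weights)
  loc_row <- integer(n)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    rows <- which(loci$class == cl)
    loc_row[idx] <- if (length(rows) == 1L) rows else
      sample(rows, length(idx), replace = TRUE,
             prob = loci$abundance_weight[rows])
  }

  lens <- unname(pmin(pmax(CANONICAL_LENGTH[cls] +
                             draw_delta(n, config$length_delta_probs),
                           config$length_range[1]), config$length_range[2]))
  shift <- draw_delta(n, config$shift_probs)
  start <- integer(n)
  strand <- character(n)
  l_start <- loci$start[loc_row]
  l_end <- loci$end[loc_row]

  hc <- which(cls == "hc_siRNA")
  if (length(hc)) {
    span <- l_end[hc] - l_start[hc] - lens[hc]
    start[hc] <- l_start[hc] +
      floor(stats::runif(length(hc)) * (span + 1L))
    strand[hc] <- sample(c("+", "-"), length(hc), replace = TRUE)
  }

  mir <- which(cls == "miRNA")
  if (length(mir)) {
    p_mat <- config$mirna_star_ratio / (config$mirna_star_ratio + 1)
    is_mat <- stats::runif(length(mir)) < p_mat
    loc_len <- l_end[mir] - l_start[mir]
    # miRNA* is the duplex partner on the 3' arm, 2-nt 3' overhang geometry
    star_off <- loc_len - MIRNA_MATURE_OFFSET - CANONICAL_LENGTH[["miRNA"]] + 2L
    start[mir] <- l_start[mir] + ifelse(is_mat, MIRNA_MATURE_OFFSET, star_off)
    strand[mir] <- "+"
  }

  tas <- which(cls == "tasiRNA")
  if (length(tas)) {
    ph <- CANONICAL_LENGTH[["tasiRNA"]]
    for (lr in unique(loc_row[tas])) {
      idx <- tas[loc_row[tas] == lr]
      loc_len <- loci$end[lr] - loci$start[lr]
      plus_off <- seq(0L, loc_len - ph, by = ph)
      minus_off <- plus_off + 2L
      minus_off <- minus_off[minus_off + ph <= loc_len]
      offs <- c(plus_off, minus_off)
      strd <- c(rep("+", length(plus_off)), rep("-", length(minus_off)))
      w <- stats::rgamma(length(offs), shape = 1)  # drawn once per locus
      reg <- sample.int(length(offs), length(idx), replace = TRUE, prob = w)
      start[idx] <- loci$start[lr] + offs[reg]
      strand[idx] <- strd[reg]
    }
  }

  start <- start + shift
  rl <- unname(ref_len[loci$reference[loc_row]])
  start <- as.integer(pmin(pmax(start, 0L), rl - lens))

  refs <- loci$reference[loc_row]
  seqs <- unname(substring(ref_seq[refs], start + 1L, start + lens))
  minus <- which(strand == "-")
  if (length(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))

  has_error <- stats::runif(n) < config$error_rate
  for (i in which(has_error)) {
    p <- sample.int(lens[i], 1L)
    old <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }

  read_id <- paste(loci$locus_id[loc_row], refs, start, strand,
                   seq_len(n), sep = "|")
  truth <- data.frame(read_id = read_id,
                      locus_id = loci$locus_id[loc_row],
                      class = cls,
                      true_reference = refs,
                      true_start = start,
                      true_strand = strand,
                      has_error = has_error,
                      stringsAsFactors = FALSE)
  reads <- data.frame(read_id = read_id, sequence = seqs,
                      has_error = has_error, stringsAsFactors = FALSE)
  rownames(truth) <- rownames(reads) <- NULL
  structure(list(reads = reads, truth = truth), class = "sim_library")
}

#' Write simulated reads as FASTQ (constant quality 'I')
#' @param reads Read data frame (or a `sim_library`).
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  if (inherits(reads, "sim_library")) reads <- reads$reads
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- strrep("I", nchar(reads$sequence))
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Write the simulation truth table as TSV
#' @param truth Truth data frame (or a `sim_library`).
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  if (inherits(truth, "sim_library")) truth <- truth$truth
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a FASTQ or FASTA file of small RNA reads
#' @param path Input path; format detected from the first character.
#' @return Data frame with `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  head1 <- readLines(path, n = 1L)
  if (length(head1) == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  first <- substr(head1, 1L, 1L)
  x <- if (identical(first, "@"))
    Biostrings::readDNAStringSet(path, format = "fastq")
  else
    Biostrings::readDNAStringSet(path, format = "fasta")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}
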