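#' Configuration for the synthetic genome generator
#'
#' Describes a synthetic genome into which small RNA source loci are
#' planted. Multi-mapping structure is created by exact (zero-divergence)
#' repeat families: a family consists of one expressed hc-siRNA "host"
#' locus whose central sub-segment (the repeat unit, about
#' `unit_fraction` of the locus and at least 100 nt) is copied, exactly,
#' to `copy_number - 1` silent decoy positions elsewhere in the genome.
#' A read falling wholly inside the unit therefore matches the genome at
#' exactly `copy_number` positions while its true origin is known, and
#' reads from the host's unique flanks are uniquely aligned, providing the
#' local context that distinguishes the expressed copy from the silent
#' ones — the situation in real repeat-rich genomes where most copies of a
#' repeat do not produce small RNAs.
#'
#' Families can be given explicitly via `repeat_families` (a data frame
#' with columns `copy_number` and `unit_length`: one host locus plus
#' `copy_number - 1` decoys per row); when `NULL` they are drawn
#' automatically so that about `family_fraction` of the hc-siRNA loci host
#' a family with copy numbers sampled uniformly from `family_copy_range`.
#'
#' @param n_references Number of reference sequences.
#' @param reference_length Length of each reference, in nt.
#' @param gc_content GC fraction of background sequence, in (0,1).
#' @param n_loci Total number of planted expressed loci.
#' @param locus_class_weights Named fractions (summing to 1) of loci
#'   assigned to the `hc_siRNA`, `miRNA` and `tasiRNA` archetypes.
#' @param family_fraction Fraction of hc-siRNA loci hosting a repeat
#'   family (ignored when `repeat_families` is supplied).
#' @param family_copy_range Integer range of total genomic copy numbers.
#' @param unit_fraction Repeat unit length as a fraction of the host
#'   locus (automatic families).
#' @param repeat_families Optional explicit family table (see above). Use
#'   `data.frame(copy_number = integer(), unit_length = integer())` for a
#'   genome with no repeat structure.
#' @param hc_length_range Length range (nt) for hc-siRNA loci.
#' @param mirna_locus_length Length (nt) of miRNA hairpin loci.
#' @param tasirna_locus_length Length (nt) of tasiRNA loci.
#' @param min_gap Minimum spacing (nt) between planted intervals; the
#'   default (300) keeps each interval outside the reach of the default
#'   five-bin placement vicinity of any other.
#' @param rng_seed Integer seed; identical configs and seeds give
#'   byte-identical genomes.
#' @return An object of class `sim_genome_config`.
#' @export
sim_genome_config <- function(n_references = 1L,
                              reference_length = 1000000L,
                              gc_content = 0.36,
                              n_loci = 200L,
                              locus_class_weights = c(hc_siRNA = 0.65,
                                                      miRNA = 0.30,
                                                      tasiRNA = 0.05),
                              family_fraction = 0.30,
                              family_copy_range = c(2L, 8L),
                              unit_fraction = 0.5,
                              repeat_families = NULL,
                              hc_length_range = c(200L, 1000L),
                              mirna_locus_length = 125L,
                              tasirna_locus_length = 140L,
                              min_gap = 300L,
                              rng_seed = 1L) {
  stopifnot(n_references >= 1L, reference_length >= 1L, n_loci >= 0L)
  if (!(gc_content > 0 && gc_content < 1))
    stop("gc_content must be strictly between 0 and 1")
  req <- c("hc_siRNA", "miRNA", "tasiRNA")
  if (!all(req %in% names(locus_class_weights)))
    stop("locus_class_weights must be named hc_siRNA, miRNA, tasiRNA")
  locus_class_weights <- locus_class_weights[req]
  if (abs(sum(locus_class_weights) - 1) > 1e-9)
    stop("locus_class_weights must sum to 1")
  if (!is.null(repeat_families)) {
    repeat_families <- as.data.frame(repeat_families)
    stopifnot(all(c("copy_number", "unit_length") %in% names(repeat_families)))
    if (nrow(repeat_families) && any(repeat_families$copy_number < 1L))
      stop("repeat family copy_number must be >= 1")
  }
  stopifnot(length(family_copy_range) == 2L,
            family_copy_range[1] >= 1L,
            family_copy_range[1] <= family_copy_range[2],
            family_fraction >= 0, family_fraction <= 1,
            unit_fraction > 0, unit_fraction <= 1,
            hc_length_range[1] <= hc_length_range[2])
  structure(list(n_references = as.integer(n_references),
                 reference_length = as.integer(reference_length),
                 gc_content = gc_content,
                 n_loci = as.integer(n_loci),
                 locus_class_weights = locus_class_weights,
                 family_fraction = family_fraction,
                 family_copy_range = as.integer(family_copy_range),
                 unit_fraction = unit_fraction,
                 repeat_families = repeat_families,
                 hc_length_range = as.integer(hc_length_range),
                 mirna_locus_length = as.integer(mirna_locus_length),
                 tasirna_locus_length = as.integer(tasirna_locus_length),
                 min_gap = as.integer(min_gap),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_genome_config")
}

#' Default synthetic genome used by the benchmark
#'
#' One 1-Mb reference carrying 200 expressed loci (65% hc-siRNA, 30%
#' miRNA, 5% tasiRNA), with 30% of the hc-siRNA loci hosting exact-copy
#' repeat families of total copy number 2-8. This yields a library with a
#' substantial multi-mapping fraction while keeping alignment and
#' placement fast on a single CPU.
#'
#' @param rng_seed Integer seed.
#' @return A `sim_genome_config`.
#' @export
default_genome_config <- function(rng_seed = 1L) {
  sim_genome_config(rng_seed = rng_seed)
}

rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

MIN_UNIT_LENGTH <- 100L

# Place k intervals of given lengths uniformly and without overlap on
# [0, ref_len), keeping at least min_gap between them and at the ends.
place_intervals <- function(lengths, ref_len, min_gap) {
  k <- length(lengths)
  if (k == 0L) return(integer(0))
  free <- ref_len - sum(lengths) - (k + 1L) * min_gap
  if (free < 0)
    stop("planted loci do not fit: need ", sum(lengths) + (k + 1L) * min_gap,
         " nt but reference is ", ref_len, " nt", call. = FALSE)
  cuts <- sort(c(0, stats::runif(k, 0, 1), 1))
  gaps <- floor(diff(cuts)[seq_len(k)] * free)
  starts <- min_gap + cumsum(c(0L, lengths[-k] + min_gap)) + cumsum(gaps)
  as.integer(starts)
}

#' Generate a synthetic genome with planted small RNA loci
#'
#' Background sequence is i.i.d. with the configured GC content. Expressed
#' loci and silent repeat decoys are placed uniformly without overlap.
#' Each repeat family's unit sequence is taken from its host locus and
#' copied verbatim to the family's decoy positions, so reads wholly inside
#' the unit match the genome at exactly `copy_number` positions; all other
#' locus sequence is random background and reads from it are effectively
#' unique in the genome. Per-locus expression levels (`abundance_weight`)
#' are drawn log-normal (meanlog 0, sdlog 1).
#'
#' @param config A [sim_genome_config()].
#' @return A list of class `sim_genome` with elements `genome` (a
#'   [Biostrings::DNAStringSet]), `loci` (data frame: `reference`,
#'   `start`, `end` 0-based half-open, `locus_id`, `class`, `strand_mode`,
#'   `family_id` (`NA` outside families), `abundance_weight`), and
#'   `repeats` (data frame of planted repeat-unit copies: `reference`,
#'   `start`, `end`, `family_id`, `role` — `host_unit` inside the
#'   expressed locus or `decoy`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_genome_config"))
  set.seed(config$rng_seed)

  w <- config$locus_class_weights
  n_hc <- round(w[["hc_siRNA"]] * config$n_loci)
  n_mir <- round(w[["miRNA"]] * config$n_loci)
  n_tas <- config$n_loci - n_hc - n_mir

  hc_lens <- if (n_hc > 0)
    sample(seq(config$hc_length_range[1], config$hc_length_range[2]),
           n_hc, replace = TRUE) else integer(0)

  # families: one host hc locus + (copy_number - 1) silent decoys each
  if (is.null(config$repeat_families)) {
    n_fam <- round(config$family_fraction * n_hc)
    fam_copies <- if (n_fam > 0)
      sample(seq(config$family_copy_range[1], config$family_copy_range[2]),
             n_fam, replace = TRUE) else integer(0)
    host_idx <- seq_len(n_fam)  # loci are shuffled later
    unit_len <- pmax(MIN_UNIT_LENGTH,
                     as.integer(round(config$unit_fraction *
                                        hc_lens[host_idx])))
    unit_len <- pmin(unit_len, hc_lens[host_idx])
  } else {
    fam_copies <- as.integer(config$repeat_families$copy_number)
    unit_len <- as.integer(config$repeat_families$unit_length)
    n_fam <- length(fam_copies)
    if (n_fam > n_hc)
      stop("more repeat families than hc-siRNA loci (", n_fam, " > ",
           n_hc, ")")
    host_idx <- seq_len(n_fam)
    # host loci must accommodate their unit
    hc_lens[host_idx] <- pmax(hc_lens[host_idx], unit_len)
  }

  cls <- c(rep("hc_siRNA", n_hc), rep("miRNA", n_mir), rep("tasiRNA", n_tas))
  len <- c(hc_lens, rep(config$mirna_locus_length, n_mir),
           rep(config$tasirna_locus_length, n_tas))
  fam_of_locus <- rep(NA_integer_, length(cls))
  fam_of_locus[host_idx] <- seq_len(n_fam)

  # decoy intervals appended after the loci
  n_loc <- length(cls)
  dec_fam <- rep(seq_len(n_fam), pmax(fam_copies - 1L, 0L))
  all_len <- c(len, unit_len[dec_fam])
  n_all <- length(all_len)

  ord <- sample.int(n_all)  # interleave loci and decoys along references
  inv <- order(ord)         # position of original i in shuffled layout
  ref_of <- sort(rep_len(seq_len(config$n_references), n_all))[inv]

  refs <- sprintf("ref%d", seq_len(config$n_references))
  seqs <- character(config$n_references)
  starts <- integer(n_all)
  for (r in seq_len(config$n_references)) {
    idx <- which(ref_of == r)
    idx <- idx[order(ord[idx])]  # placement order = shuffled order
    starts[idx] <- place_intervals(all_len[idx], config$reference_length,
                                   config$min_gap)
    seqs[r] <- paste(rand_bases(config$reference_length, config$gc_content),
                     collapse = "")
  }

  # carve each family's unit out of its host locus and copy to decoys
  unit_off <- integer(n_fam)
  for (f in seq_len(n_fam)) {
    h <- host_idx[f]
    unit_off[f] <- if (len[h] > unit_len[f])
      sample.int(len[h] - unit_len[f] + 1L, 1L) - 1L else 0L
    unit_seq <- substr(seqs[ref_of[h]],
                       starts[h] + unit_off[f] + 1L,
                       starts[h] + unit_off[f] + unit_len[f])
    for (d in n_loc + which(dec_fam == f))
      substr(seqs[ref_of[d]], starts[d] + 1L,
             starts[d] + unit_len[f]) <- unit_seq
  }

  fam_ids <- if (n_fam > 0) sprintf("F%03d", seq_len(n_fam)) else character(0)
  loci <- data.frame(reference = refs[ref_of[seq_len(n_loc)]],
                     start = starts[seq_len(n_loc)],
                     end = starts[seq_len(n_loc)] + len,
                     locus_id = sprintf("L%04d", seq_len(n_loc)),
                     class = cls,
                     strand_mode = ifelse(cls == "miRNA", "plus_hairpin",
                                          "both"),
                     family_id = fam_ids[fam_of_locus],
                     abundance_weight = stats::rlnorm(n_loc, 0, 1),
                     stringsAsFactors = FALSE)
  host_units <- if (n_fam > 0) data.frame(
    reference = refs[ref_of[host_idx]],
    start = starts[host_idx] + unit_off,
    end = starts[host_idx] + unit_off + unit_len,
    family_id = fam_ids,
    role = "host_unit", stringsAsFactors = FALSE) else NULL
  decoys <- if (length(dec_fam)) data.frame(
    reference = refs[ref_of[n_loc + seq_along(dec_fam)]],
    start = starts[n_loc + seq_along(dec_fam)],
    end = starts[n_loc + seq_along(dec_fam)] + unit_len[dec_fam],
    family_id = fam_ids[dec_fam],
    role = "decoy", stringsAsFactors = FALSE) else NULL
  repeats <- if (is.null(host_units) && is.null(decoys))
    data.frame(reference = character(0), start = integer(0),
               end = integer(0), family_id = character(0),
               role = character(0))
  else rbind(host_units, decoys)
  rownames(repeats) <- NULL

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- refs
  structure(list(genome = genome, loci = loci, repeats = repeats),
            class = "sim_genome")
}

#' Write a genome to FASTA (60-column wrap)
#' @param genome A [Biostrings::DNAStringSet] (or `sim_genome`).
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Write a locus table as BED6+1
#'
#' Columns: reference, start, end, locus_id, abundance rank (1 = most
#' abundant), strand `.` (loci emit reads from both strands or a hairpin),
#' and the locus class.
#' @param loci Locus data frame from [generate_genome()].
#' @param path Output path.
#' @export
write_loci_bed <- function(loci, path) {
  if (inherits(loci, "sim_genome")) loci <- loci$loci
  bed <- data.frame(loci$reference, loci$start, loci$end, loci$locus_id,
                    rank(-loci$abundance_weight, ties.method = "first"),
                    ".", loci$class)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
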