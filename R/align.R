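#' Build an exact-match query index over a genome
#'
#' Wraps the reference sequences for repeated exact-substring queries on
#' both strands, for read lengths within `length_range`. Minus-strand hits
#' are reported by the leftmost plus-strand coordinate of the reverse
#' complement's match, as in SAM.
#'
#' @param genome A [Biostrings::DNAStringSet], named character vector, or
#'   `sim_genome`.
#' @param length_range Two integers, the allowed query lengths (nt).
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(genome, length_range = c(20L, 25L)) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (length(genome) == 0L) stop("cannot index an empty genome")
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  structure(list(genome = genome,
                 ref_names = names(genome),
                 ref_lengths = stats::setNames(Biostrings::width(genome),
                                               names(genome)),
                 length_range = as.integer(length_range)),
            class = "genome_index")
}

# all exact-match sites for a set of equal-length unique sequences;
# returns data.frame(sequence, reference, pos, strand)
match_fixed_width <- function(seqs, index) {
  pats <- Biostrings::DNAStringSet(seqs)
  rcs <- Biostrings::reverseComplement(pats)
  pd_fwd <- Biostrings::PDict(pats)
  pd_rev <- Biostrings::PDict(rcs)
  out <- vector("list", 2L * length(index$ref_names))
  k <- 0L
  for (r in index$ref_names) {
    subject <- index$genome[[r]]
    for (strand in c("+", "-")) {
      pd <- if (strand == "+") pd_fwd else pd_rev
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      cnt <- lengths(starts)
      if (sum(cnt)) {
        k <- k + 1L
        out[[k]] <- data.frame(
          sequence = rep(seqs, cnt),
          reference = r,
          pos = unlist(starts, use.names = FALSE) - 1L,
          strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(sequence = character(0), reference = character(0),
                      pos = integer(0), strand = character(0)))
  do.call(rbind, out[seq_len(k)])
}

new_alignments <- function(reads, sites, ref_lengths) {
  rownames(reads) <- rownames(sites) <- NULL
  structure(list(reads = reads, sites = sites, ref_lengths = ref_lengths),
            class = "srna_alignments")
}

#' Construct alignment groups from explicit tables
#'
#' Builds the container produced by [align_reads()] from per-read and
#' per-site tables, for alignments computed elsewhere or constructed by
#' hand (e.g. worked examples). Sites of one read must be unique on
#' (reference, pos, strand) and lie within the reference bounds.
#'
#' @param reads Data frame with `read_id`, `sequence`, `n` (MMAP-value)
#'   and `overflow`; `n` and `overflow` default to the site count and
#'   `FALSE` when missing.
#' @param sites Data frame with `read_id`, `reference`, `pos` (0-based
#'   leftmost), `strand` (`+`/`-`), `length`.
#' @param ref_lengths Named integer vector of reference lengths.
#' @return An `srna_alignments` object.
#' @export
alignment_groups <- function(reads, sites, ref_lengths) {
  reads <- as.data.frame(reads)
  sites <- as.data.frame(sites)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)),
            all(c("read_id", "reference", "pos", "strand", "length") %in%
                  names(sites)),
            !is.null(names(ref_lengths)))
  if (anyDuplicated(reads$read_id))
    stop("duplicate read_ids")
  if (anyDuplicated(sites[c("read_id", "reference", "pos", "strand")]))
    stop("duplicate sites within a read")
  if (!all(sites$read_id %in% reads$read_id))
    stop("sites reference unknown read_ids")
  if (!all(sites$reference %in% names(ref_lengths)))
    stop("sites reference unknown reference names")
  rl <- ref_lengths[sites$reference]
  if (any(sites$pos < 0L | sites$pos + sites$length > rl))
    stop("site coordinates outside reference bounds")
  cnt <- table(sites$read_id)
  if (is.null(reads$n)) {
    reads$n <- as.integer(cnt[reads$read_id])
    reads$n[is.na(reads$n)] <- 0L
  }
  if (is.null(reads$overflow)) reads$overflow <- FALSE
  new_alignments(reads, sites, ref_lengths)
}

#' Enumerate all exact-match alignment positions for a set of reads
#'
#' For each read, all positions on both strands of the genome where the
#' read matches exactly are reported; the number of such positions is the
#' read's MMAP-value `n`. Sites are ordered by (reference, position,
#' strand). When a read has more than `max_sites` positions, its site list
#' is truncated to the first `max_sites` and the read is flagged
#' `overflow`; such reads are later marked unmapped by placement. Reads
#' containing characters outside A/C/G/T get zero sites.
#'
#' @param reads Data frame with `read_id` and `sequence` (a named character
#'   vector is also accepted).
#' @param index A [genome_index()].
#' @param max_sites Reporting cap per read (default 50).
#' @return An object of class `srna_alignments`: a list with `reads` (data
#'   frame `read_id`, `sequence`, `n`, `overflow`), `sites` (data frame
#'   `read_id`, `reference`, `pos` 0-based, `strand`, `length`), and
#'   `ref_lengths`.
#' @export
align_reads <- function(reads, index, max_sites = 50L) {
  stopifnot(inherits(index, "genome_index"), max_sites >= 1L)
  if (is.character(reads))
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(reads$read_id))
    stop("duplicate read_ids: ",
         reads$read_id[duplicated(reads$read_id)][1])
  lens <- nchar(reads$sequence)
  bad <- which(lens < index$length_range[1] | lens > index$length_range[2])
  if (length(bad))
    stop("read length ", lens[bad[1]], " outside index range for read ",
         reads$read_id[bad[1]])

  valid <- grepl("^[ACGT]+$", reads$sequence)
  uniq <- unique(reads$sequence[valid])
  hit_tabs <- list()
  if (length(uniq)) {
    by_len <- split(uniq, nchar(uniq))
    hit_tabs <- lapply(by_len, match_fixed_width, index = index)
  }
  hits <- if (length(hit_tabs)) do.call(rbind, hit_tabs) else
    data.frame(sequence = character(0), reference = character(0),
               pos = integer(0), strand = character(0))
  # deterministic site order within a sequence: reference, pos, strand
  if (nrow(hits))
    hits <- hits[order(hits$sequence, hits$reference, hits$pos,
                       match(hits$strand, c("+", "-"))), , drop = FALSE]

  n_by_seq <- table(hits$sequence)
  n_all <- as.integer(n_by_seq[reads$sequence])
  n_all[is.na(n_all)] <- 0L
  overflow <- n_all > max_sites
  n_capped <- pmin(n_all, as.integer(max_sites))

  # expand per-sequence site blocks to per-read site lists (capped)
  sites <- data.frame(read_id = character(0), reference = character(0),
                      pos = integer(0), strand = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    blk_start <- c(1L, which(hits$sequence[-1] != hits$sequence[-nrow(hits)]) + 1L)
    names(blk_start) <- hits$sequence[blk_start]
    take <- which(n_capped > 0L)
    if (length(take)) {
      firsts <- blk_start[reads$sequence[take]]
      row_idx <- sequence(n_capped[take]) +
        rep(firsts, n_capped[take]) - 1L
      sites <- data.frame(
        read_id = rep(reads$read_id[take], n_capped[take]),
        reference = hits$reference[row_idx],
        pos = hits$pos[row_idx],
        strand = hits$strand[row_idx],
        length = nchar(rep(reads$sequence[take], n_capped[take])),
        stringsAsFactors = FALSE)
    }
  }
  rd <- data.frame(read_id = reads$read_id, sequence = reads$sequence,
                   n = n_capped, overflow = overflow,
                   stringsAsFactors = FALSE)
  new_alignments(rd, sites, index$ref_lengths)
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one read.
#' @param read_id Read identifier.
#' @param sequence Read sequence.
#' @inheritParams align_reads
#' @return An `srna_alignments` object holding one read.
#' @export
align_read <- function(read_id, sequence, index, max_sites = 50L) {
  align_reads(data.frame(read_id = read_id, sequence = sequence,
                         stringsAsFactors = FALSE), index, max_sites)
}
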