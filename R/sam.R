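#' @importFrom utils packageVersion
sam_header <- function(ref_lengths, extra = character(0)) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
            as.integer(ref_lengths)),
    sprintf("@PG\tID:srnaplace\tPN:srnaplace\tVN:%s",
            as.character(utils::packageVersion("srnaplace"))),
    extra)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write an all-alignment SAM file
#'
#' Emits every candidate site of every read, all flagged secondary
#' (0x100), pending placement; reads with zero sites are written as
#' unmapped records (0x4). Minus-strand records carry the reverse
#' complement of the read, per the SAM convention. Custom tags: `XV:i`
#' (MMAP-value), `XF:i` (1 when the site list was truncated at the
#' reporting cap).
#'
#' @param aln An `srna_alignments` object from [align_reads()] or
#'   [read_alignment_sam()].
#' @param path Output path.
#' @export
write_alignment_sam <- function(aln, path) {
  stopifnot(inherits(aln, "srna_alignments"))
  rd <- aln$reads
  st <- aln$sites
  i <- match(st$read_id, rd$read_id)
  seq_out <- ifelse(st$strand == "+", rd$sequence[i],
                    revcomp_chr(rd$sequence[i]))
  mapped <- sprintf("%s\t%d\t%s\t%d\t0\t%dM\t*\t0\t0\t%s\t*\tXV:i:%d\tXF:i:%d",
                    st$read_id,
                    256L + ifelse(st$strand == "-", 16L, 0L),
                    st$reference, st$pos + 1L, st$length, seq_out,
                    rd$n[i], as.integer(rd$overflow[i]))
  un <- rd[rd$n == 0L, , drop = FALSE]
  unmapped <- if (nrow(un))
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*\tXV:i:0\tXF:i:0",
            un$read_id, un$sequence) else character(0)
  writeLines(c(sam_header(aln$ref_lengths), mapped, unmapped), path)
  invisible(path)
}

#' Read an all-alignment SAM file into alignment groups
#'
#' Records are grouped by query name (records for one read need not be
#' adjacent); SAM 1-based positions become internal 0-based coordinates and
#' strand is taken from FLAG bit 0x10. Unmapped records yield groups with
#' zero sites. `@SQ` header lines are required for reference lengths.
#' Duplicate (reference, pos, strand) records for a read are collapsed.
#'
#' @param path Path to a SAM file with all candidate records per read
#'   (bowtie `-a` convention).
#' @param max_sites Reporting cap; groups with more sites are truncated and
#'   flagged overflow (an `XF:i:1` tag on any record also flags overflow).
#' @return An `srna_alignments` object.
#' @export
read_alignment_sam <- function(path, max_sites = 50L) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[is_hdr & startsWith(lines, "@SQ")]
  if (length(sq) == 0L) stop("SAM file lacks @SQ header lines")
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  ref_lengths <- stats::setNames(ln, sn)

  body_idx <- which(!is_hdr & nzchar(lines))
  if (length(body_idx) == 0L)
    return(new_alignments(
      data.frame(read_id = character(0), sequence = character(0),
                 n = integer(0), overflow = logical(0)),
      data.frame(read_id = character(0), reference = character(0),
                 pos = integer(0), strand = character(0),
                 length = integer(0)),
      ref_lengths))
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM line at line ", body_idx[which(nf < 11L)[1]],
         ": fewer than 11 fields")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  if (anyNA(flag))
    stop("malformed SAM line at line ", body_idx[which(is.na(flag))[1]],
         ": non-numeric FLAG")
  rname <- vapply(fields, `[[`, "", 3L)
  pos1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  seqf <- vapply(fields, `[[`, "", 10L)
  unmapped <- bitwAnd(flag, 4L) != 0L
  minus <- bitwAnd(flag, 16L) != 0L
  if (any(!unmapped & (is.na(pos1) | pos1 < 1L)))
    stop("malformed SAM line at line ",
         body_idx[which(!unmapped & (is.na(pos1) | pos1 < 1L))[1]],
         ": invalid POS")
  if (any(!unmapped & !(rname %in% sn)))
    stop("malformed SAM line at line ",
         body_idx[which(!unmapped & !(rname %in% sn))[1]],
         ": RNAME not in @SQ headers")
  overflow_tag <- grepl("\tXF:i:1(\t|$)", lines[body_idx])

  # read sequence in read orientation (reverse complement minus records)
  read_seq <- seqf
  rc_idx <- which(minus & seqf != "*")
  if (length(rc_idx)) read_seq[rc_idx] <- revcomp_chr(seqf[rc_idx])

  ids <- unique(qname)
  seq_by_read <- rep(NA_character_, length(ids))
  names(seq_by_read) <- ids
  known <- read_seq != "*"
  seq_by_read[qname[known]] <- read_seq[known]
  lens_by_rec <- ifelse(seqf == "*", NA_integer_, nchar(seqf))
  n_lens <- tapply(lens_by_rec, qname,
                   function(v) length(unique(v[!is.na(v)])))
  if (any(n_lens > 1L, na.rm = TRUE))
    stop("inconsistent sequence lengths across records for read ",
         names(n_lens)[which(n_lens > 1L)[1]])

  m <- !unmapped
  st <- data.frame(read_id = qname[m], reference = rname[m],
                   pos = pos1[m] - 1L,
                   strand = ifelse(minus[m], "-", "+"),
                   length = nchar(read_seq[m]),
                   stringsAsFactors = FALSE)
  st <- st[!duplicated(st[c("read_id", "reference", "pos", "strand")]), ,
           drop = FALSE]
  st <- st[order(match(st$read_id, ids), st$reference, st$pos,
                 match(st$strand, c("+", "-"))), , drop = FALSE]
  n_by_read <- stats::setNames(integer(length(ids)), ids)
  tb <- table(st$read_id)
  n_by_read[names(tb)] <- as.integer(tb)
  overflow <- stats::setNames(logical(length(ids)), ids)
  if (any(overflow_tag)) {
    ov_ids <- unique(qname[overflow_tag])
    overflow[ov_ids] <- TRUE
  }
  over_cap <- names(n_by_read)[n_by_read > max_sites]
  if (length(over_cap)) {
    overflow[over_cap] <- TRUE
    keep <- unlist(lapply(split(seq_len(nrow(st)), st$read_id), function(ix)
      ix[seq_len(min(length(ix), max_sites))]), use.names = FALSE)
    st <- st[sort(keep), , drop = FALSE]
    tb <- table(st$read_id)
    n_by_read[names(tb)] <- as.integer(tb)
  }
  rd <- data.frame(read_id = ids,
                   sequence = unname(seq_by_read),
                   n = unname(n_by_read[ids]),
                   overflow = unname(overflow[ids]),
                   stringsAsFactors = FALSE)
  new_alignments(rd, st, ref_lengths)
}

#' Write placement results as SAM
#'
#' Each placed read gets exactly one primary record at its chosen site; all
#' of its other candidate sites are emitted as secondary records (0x100).
#' Suppressed, overflow, mode-N-discarded and unalignable reads are emitted
#' as unmapped records (0x4). Custom tags: `XV:i` MMAP-value, `XP:f`
#' placement probability of the chosen site (primary records only), `XC:A`
#' status — `P` placed, `T` tie-suppressed, `O` overflow, `N` discarded by
#' mode N, `U` no valid alignment.
#'
#' @param placements An `srna_placements` object from [place_library()].
#' @param path Output path.
#' @export
write_placed_sam <- function(placements, path) {
  stopifnot(inherits(placements, "srna_placements"))
  dec <- placements$decisions
  st <- placements$sites
  rd <- placements$reads
  i <- match(st$read_id, rd$read_id)
  j <- match(st$read_id, dec$read_id)
  placed <- dec$status == "P"
  is_primary <- placed[j] &
    st$reference == dec$chosen_reference[j] &
    st$pos == dec$chosen_pos[j] & st$strand == dec$chosen_strand[j]
  emit <- placed[j]  # sites of unplaced reads are dropped; reads go unmapped
  seq_out <- ifelse(st$strand == "+", rd$sequence[i],
                    revcomp_chr(rd$sequence[i]))
  flag <- ifelse(is_primary, 0L, 256L) + ifelse(st$strand == "-", 16L, 0L)
  tag_p <- ifelse(is_primary,
                  sprintf("\tXP:f:%.6g", dec$probability[j]), "")
  mapped <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tXV:i:%d\tXC:A:%s%s",
                    st$read_id, flag, st$reference, st$pos + 1L,
                    ifelse(is_primary, 255L, 0L), st$length, seq_out,
                    dec$n[j], dec$status[j], tag_p)[emit]
  un <- dec[dec$status != "P", , drop = FALSE]
  k <- match(un$read_id, rd$read_id)
  unmapped <- if (nrow(un))
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*\tXV:i:%d\tXC:A:%s",
            un$read_id, rd$sequence[k], un$n, un$status) else character(0)
  writeLines(c(sam_header(placements$ref_lengths), mapped, unmapped), path)
  invisible(path)
}
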