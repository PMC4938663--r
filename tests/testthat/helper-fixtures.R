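# Independent brute-force utilities and hand-built fixtures.
# The oracle scanner is pure R (vectorised substring comparison) and shares
# no code with the package's Biostrings-based matcher.

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all exact-match sites of `query` in a named character genome, both strands
brute_sites <- function(genome_chr, query) {
  k <- nchar(query)
  out <- list()
  for (r in names(genome_chr)) {
    s <- genome_chr[[r]]
    n <- nchar(s)
    if (n < k) next
    kmers <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc_chr(query)
      hits <- which(kmers == q)
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(
          reference = r, pos = hits - 1L, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(reference = character(0), pos = integer(0),
                      strand = character(0)))
  df <- do.call(rbind, out)
  df[order(df$reference, df$pos, match(df$strand, c("+", "-"))), ,
     drop = FALSE]
}

random_genome <- function(len, seed, name = "chr") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  stats::setNames(s, name)
}

# hand-built alignment container on the public data contract
make_alignments <- function(reads, sites, ref_lengths) {
  rownames(reads) <- rownames(sites) <- NULL
  structure(list(reads = reads, sites = sites, ref_lengths = ref_lengths),
            class = "srna_alignments")
}

# a library of single-site reads at given positions (vicinity furniture)
unique_reads_at <- function(prefix, reference, positions, len = 21L) {
  n <- length(positions)
  reads <- data.frame(read_id = sprintf("%s%03d", prefix, seq_len(n)),
                      sequence = strrep("A", len), n = 1L,
                      overflow = FALSE, stringsAsFactors = FALSE)
  sites <- data.frame(read_id = reads$read_id, reference = reference,
                      pos = as.integer(positions), strand = "+",
                      length = len, stringsAsFactors = FALSE)
  list(reads = reads, sites = sites)
}

# the two-candidate worked example: a read with sites at `posA` and `posB`
# plus configurable vicinity furniture; returns the combined alignments and
# the focal group
worked_example <- function(posA = 1000L, posB = 5000L,
                           unique_near_A = 7L, unique_near_B = 1L,
                           mmap2_near_B = 0L, ref_len = 20000L) {
  furn_A <- unique_reads_at("uA", "chr1", posA + seq_len(unique_near_A))
  furn_B <- unique_reads_at("uB", "chr1", posB + seq_len(unique_near_B))
  reads <- rbind(furn_A$reads, furn_B$reads)
  sites <- rbind(furn_A$sites, furn_B$sites)
  if (mmap2_near_B > 0) {
    # two-site reads with one site near B and the partner far away
    for (i in seq_len(mmap2_near_B)) {
      id <- sprintf("m2_%02d", i)
      reads <- rbind(reads, data.frame(read_id = id, sequence = strrep("C", 21L),
                                       n = 2L, overflow = FALSE))
      sites <- rbind(sites,
                     data.frame(read_id = id, reference = "chr1",
                                pos = c(posB + 10L + i, 15000L + 30L * i),
                                strand = "+", length = 21L))
    }
  }
  focal <- data.frame(read_id = "green", sequence = strrep("G", 21L),
                      n = 2L, overflow = FALSE, stringsAsFactors = FALSE)
  focal_sites <- data.frame(read_id = "green", reference = "chr1",
                            pos = c(posA, posB), strand = "+",
                            length = 21L, stringsAsFactors = FALSE)
  aln <- make_alignments(rbind(reads, focal), rbind(sites, focal_sites),
                         c(chr1 = ref_len))
  group <- make_alignments(focal, focal_sites, c(chr1 = ref_len))
  list(aln = aln, group = group)
}

tiny_sim <- function(seed = 11L, n_reads = 2000L,
                     genome_config = sim_genome_config(
                       reference_length = 80000L, n_loci = 20L,
                       min_gap = 300L, rng_seed = seed)) {
  g <- generate_genome(genome_config)
  lib <- simulate_library(g, config = sim_library_config(
    n_reads = n_reads, rng_seed = seed + 1L))
  list(genome = g, library = lib)
}
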