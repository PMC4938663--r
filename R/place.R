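#' Placement configuration
#'
#' Controls local-context weighting and primary-alignment selection.
#' The genome is divided into `bin_size`-nt bins; the vicinity of an
#' alignment is the `window_bins`-bin window centered on the bin holding its
#' leftmost aligned nucleotide (with the defaults, a ~250-nt window). Modes:
#' `"U"` weights candidate sites by unique-read counts in their vicinities,
#' `"F"` by fractional counts where every alignment contributes one over its
#' read's MMAP-value, `"R"` places uniformly at random, and `"N"` discards
#' all multi-mapping reads. In modes U and F, reads whose computed
#' probabilities are all equal remain a random guess: they are placed
#' uniformly when they have at most `tie_suppression_threshold` candidate
#' positions and are otherwise suppressed (marked unmapped). Reads with more
#' than `max_sites` candidate positions are never placed.
#'
#' @param mode One of `"U"`, `"F"`, `"R"`, `"N"`.
#' @param bin_size Bin width in nt (default 50).
#' @param window_bins Odd number of bins per vicinity (default 5).
#' @param max_sites Reporting cap on candidate positions (default 50).
#' @param tie_suppression_threshold Maximum MMAP-value still placed at
#'   random when all probabilities are tied (default 3).
#' @param rng_seed Integer seed for the weighted random selection.
#' @return An object of class `placement_config`.
#' @export
placement_config <- function(mode = c("U", "F", "R", "N"),
                             bin_size = 50L,
                             window_bins = 5L,
                             max_sites = 50L,
                             tie_suppression_threshold = 3L,
                             rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(bin_size >= 1L, window_bins >= 1L, window_bins %% 2L == 1L,
            max_sites >= 1L, tie_suppression_threshold >= 1L)
  structure(list(mode = mode, bin_size = as.integer(bin_size),
                 window_bins = as.integer(window_bins),
                 max_sites = as.integer(max_sites),
                 tie_suppression_threshold =
                   as.integer(tie_suppression_threshold),
                 rng_seed = as.integer(rng_seed)),
            class = "placement_config")
}

#' Bin index of an alignment
#'
#' An alignment belongs wholly to the bin of its leftmost aligned
#' nucleotide, regardless of strand; reads spanning a bin boundary are not
#' pro-rated.
#' @param pos 0-based leftmost aligned position(s).
#' @param bin_size Bin width in nt.
#' @return Integer bin indices (0-based).
#' @export
bin_of <- function(pos, bin_size = 50L) {
  as.integer(pos) %/% as.integer(bin_size)
}

# windowed sums of a bin vector: W[b] = sum v[b-h .. b+h], truncated at ends
window_sum <- function(v, half) {
  n <- length(v)
  if (n == 0L) return(numeric(0))
  S <- cumsum(v)
  hi <- pmin(seq_len(n) + half, n)
  lo <- seq_len(n) - half
  S[hi] - ifelse(lo <= 1L, 0, S[pmax(lo - 1L, 1L)])
}

#' Build per-bin unique and fractional read tallies
#'
#' Single pass over every candidate site in the library: each site of a
#' read with MMAP-value `n` adds `1/n` to the fractional tally `f` of its
#' bin, and sites of uniquely aligned reads (`n = 1`) additionally add 1 to
#' the unique tally `u`. Reads over the reporting cap (overflow) and reads
#' with no sites contribute nothing. Each retained read thus contributes a
#' total weight of exactly 1 to `f` across the genome.
#'
#' @param aln An `srna_alignments` object.
#' @param config A [placement_config()].
#' @return An object of class `bin_tallies`: per-reference numeric vectors
#'   `u` and `f` over bins, plus precomputed windowed sums.
#' @export
build_tallies <- function(aln, config) {
  stopifnot(inherits(aln, "srna_alignments"),
            inherits(config, "placement_config"))
  bs <- config$bin_size
  half <- (config$window_bins - 1L) %/% 2L
  nbins <- pmax(1L, as.integer(ceiling(aln$ref_lengths / bs)))
  names(nbins) <- names(aln$ref_lengths)
  rd <- aln$reads
  keep_reads <- rd$read_id[rd$n >= 1L & !rd$overflow]
  st <- aln$sites[aln$sites$read_id %in% keep_reads, , drop = FALSE]
  n_of <- rd$n[match(st$read_id, rd$read_id)]
  bin <- bin_of(st$pos, bs)
  u <- f <- lapply(nbins, numeric)
  for (r in unique(st$reference)) {
    in_r <- st$reference == r
    fr <- rowsum(1 / n_of[in_r], bin[in_r])
    f[[r]][as.integer(rownames(fr)) + 1L] <- fr[, 1L]
    uu <- in_r & n_of == 1L
    if (any(uu)) {
      ur <- rowsum(rep(1, sum(uu)), bin[uu])
      u[[r]][as.integer(rownames(ur)) + 1L] <- ur[, 1L]
    }
  }
  structure(list(u = u, f = f,
                 wu = lapply(u, window_sum, half = half),
                 wf = lapply(f, window_sum, half = half),
                 bin_size = bs, window_bins = config$window_bins,
                 nbins = nbins),
            class = "bin_tallies")
}

# windowed tally lookups for a vector of sites; returns data.frame(u, f)
lookup_vicinity <- function(reference, pos, tallies) {
  bin <- bin_of(pos, tallies$bin_size) + 1L
  u <- f <- numeric(length(pos))
  for (r in unique(reference)) {
    in_r <- reference == r
    u[in_r] <- tallies$wu[[r]][bin[in_r]]
    f[in_r] <- tallies$wf[[r]][bin[in_r]]
  }
  data.frame(u = u, f = f)
}

#' Vicinity weights of an alignment site
#'
#' Sums the unique (`u`) and fractional (`f`) bin tallies over the
#' `window_bins` bins centered on the site's bin, truncated at reference
#' ends. When `exclude_group` is given (the alignment group of the read
#' being placed, whose sites were part of the tallies), that read's own
#' contributions falling inside the window are subtracted.
#'
#' @param site A one-row data frame (or list) with `reference` and `pos`.
#' @param tallies A [build_tallies()] result.
#' @param exclude_group Optional `srna_alignments` holding the read to
#'   exclude.
#' @return A list with `u` and `f` vicinity weights.
#' @export
vicinity_weight <- function(site, tallies, exclude_group = NULL) {
  vic <- lookup_vicinity(site$reference, site$pos, tallies)
  u <- vic$u
  f <- vic$f
  if (!is.null(exclude_group)) {
    half <- (tallies$window_bins - 1L) %/% 2L
    b0 <- bin_of(site$pos, tallies$bin_size)
    gs <- exclude_group$sites
    n <- exclude_group$reads$n[1]
    inwin <- gs$reference == site$reference &
      abs(bin_of(gs$pos, tallies$bin_size) - b0) <= half
    f <- f - sum(inwin) / n
    if (n == 1L) u <- u - sum(inwin)
  }
  list(u = u, f = f)
}

rel_tied <- function(w, tol = 1e-9) {
  mx <- max(w)
  mx <= 0 || (mx - min(w)) <= tol * mx
}

#' Placement probabilities for one alignment group
#'
#' Computes the probability that the read originated from each of its
#' candidate sites. Mode `R` is uniform `1/n`. Mode `U` is proportional to
#' the count of uniquely aligned reads in each site's vicinity; mode `F` is
#' proportional to the fractional tally, where each neighbouring alignment
#' contributes one over its read's MMAP-value. In modes U and F the read's
#' own contributions to the tallies are excluded (`exclude_self`), and when
#' every site's weight is zero or all weights are equal within relative
#' tolerance `1e-9` the result is a tie, to be resolved by
#' [choose_primary()].
#'
#' @param group An `srna_alignments` holding exactly one read with
#'   `1 <= n <= max_sites`.
#' @param tallies A [build_tallies()] result (built from the full library,
#'   including this read, unless `exclude_self = FALSE`).
#' @param config A [placement_config()] with mode `R`, `U` or `F`.
#' @param exclude_self Subtract the read's own tally contributions.
#' @return A list with `p` (numeric probabilities summing to 1, or `NULL`
#'   on a tie), `tie` (logical), and `mode`.
#' @export
placement_probabilities <- function(group, tallies, config,
                                    exclude_self = TRUE) {
  stopifnot(inherits(group, "srna_alignments"),
            nrow(group$reads) == 1L)
  n <- group$reads$n[1]
  if (n < 1L || group$reads$overflow[1])
    stop("placement probabilities require 1 <= n <= max_sites")
  if (config$mode == "N")
    stop("mode N discards MMAP reads upstream; no probabilities defined")
  if (config$mode == "R")
    return(list(p = rep(1 / n, n), tie = FALSE, mode = "R"))
  excl <- if (exclude_self) group else NULL
  w <- vapply(seq_len(n), function(i) {
    vw <- vicinity_weight(group$sites[i, ], tallies, exclude_group = excl)
    if (config$mode == "U") vw$u else vw$f
  }, numeric(1))
  if (rel_tied(w)) return(list(p = NULL, tie = TRUE, mode = config$mode))
  list(p = w / sum(w), tie = FALSE, mode = config$mode)
}

#' Select the primary alignment for one read
#'
#' Samples one candidate site from the categorical distribution given by
#' the placement probabilities. Tied reads are placed uniformly at random
#' when their MMAP-value is at most the suppression threshold and are
#' otherwise suppressed (marked unmapped); overflow groups are always
#' unmapped. Uses the current RNG state.
#'
#' @param group An `srna_alignments` holding exactly one read.
#' @param probs A [placement_probabilities()] result (ignored for `n = 1`
#'   and overflow groups).
#' @param config A [placement_config()].
#' @return A list of class `placement_decision`: `read_id`,
#'   `probabilities` (numeric, or empty when suppressed), `chosen` (site
#'   index, or `"SUPPRESSED"` / `"UNMAPPED_OVERFLOW"`), and `mode`.
#' @export
choose_primary <- function(group, probs = NULL, config) {
  stopifnot(inherits(group, "srna_alignments"), nrow(group$reads) == 1L)
  n <- group$reads$n[1]
  dec <- function(chosen, p) structure(
    list(read_id = group$reads$read_id[1], probabilities = p,
         chosen = chosen, mode = config$mode), class = "placement_decision")
  if (group$reads$overflow[1]) return(dec("UNMAPPED_OVERFLOW", numeric(0)))
  if (n == 1L) return(dec(1L, 1.0))
  if (isTRUE(probs$tie)) {
    if (n > config$tie_suppression_threshold)
      return(dec("SUPPRESSED", numeric(0)))
    return(dec(sample.int(n, 1L), rep(1 / n, n)))
  }
  stopifnot(abs(sum(probs$p) - 1) < 1e-9)
  dec(sample.int(n, 1L, prob = probs$p), probs$p)
}

# categorical sampling within consecutive groups defined by sizes g;
# w >= 0 site weights with positive per-group sums; returns global row index
sample_grouped <- function(w, g) {
  if (length(g) == 0L) return(integer(0))
  ends <- cumsum(g)
  starts <- ends - g + 1L
  cw <- cumsum(w)
  base <- rep(c(0, cw[ends[-length(ends)]]), g)
  cw <- cw - base
  denom <- cw[ends]
  t_ <- stats::runif(length(g)) * denom
  hit <- cw >= rep(t_, g)
  grp <- rep(seq_along(g), g)
  idx <- which(hit)
  idx[!duplicated(grp[idx])]
}

#' Place every read of a library
#'
#' The complete placement pass: bin tallies are computed once from the full
#' all-alignment map (no iterative re-weighting), then one primary
#' alignment is selected per eligible read by weighted random selection
#' according to the configured mode. Mode `N` places unique reads only and
#' marks every multi-mapping read unmapped. Reads over the reporting cap
#' are unmapped with a distinct overflow status; in modes U/F, tied reads
#' with MMAP-value above the suppression threshold are suppressed.
#'
#' @param aln An `srna_alignments` object for the whole library.
#' @param config A [placement_config()].
#' @return An object of class `srna_placements`: `decisions` (data frame:
#'   `read_id`, `n`, `overflow`, `status` one of `P` placed, `T`
#'   tie-suppressed, `O` overflow, `N` discarded by mode N, `U` no valid
#'   alignment; `chosen_reference`, `chosen_pos`, `chosen_strand`,
#'   `probability` of the chosen site), plus the input `sites`, `reads`,
#'   `ref_lengths` and the `config`.
#' @export
place_library <- function(aln, config) {
  stopifnot(inherits(aln, "srna_alignments"),
            inherits(config, "placement_config"))
  rd <- aln$reads
  if (anyDuplicated(rd$read_id))
    stop("duplicate read_ids in alignment input")
  set.seed(config$rng_seed)
  nr <- nrow(rd)
  status <- rep("P", nr)
  status[rd$n == 0L] <- "U"
  status[rd$overflow] <- "O"
  if (config$mode == "N") status[rd$n > 1L & !rd$overflow] <- "N"

  st <- aln$sites
  site_read <- match(st$read_id, rd$read_id)

  # singletons place trivially at their only site
  prob_chosen <- rep(NA_real_, nr)
  chosen_row <- rep(NA_integer_, nr)  # row into st
  single <- which(rd$n == 1L & !rd$overflow)
  chosen_row[single] <- match(rd$read_id[single], st$read_id)
  prob_chosen[single] <- 1.0

  todo <- which(status == "P" & rd$n >= 2L)
  if (length(todo) && config$mode != "N") {
    in_todo <- site_read %in% todo
    sub <- which(in_todo)
    sub_read <- site_read[sub]
    # sites of one read are contiguous and in read order by construction;
    # enforce it so grouped operations are valid
    ord <- order(match(sub_read, todo))
    sub <- sub[ord]
    sub_read <- sub_read[ord]
    g <- as.integer(table(factor(sub_read, levels = todo)))

    if (config$mode == "R") {
      w <- rep(1, length(sub))
      tie <- rep(FALSE, length(todo))
    } else {
      tallies <- build_tallies(aln, config)
      vic <- lookup_vicinity(st$reference[sub], st$pos[sub], tallies)
      w <- if (config$mode == "U") vic$u else vic$f
      if (config$mode == "F") {
        # subtract each read's own 1/n contributions within the window
        half <- (config$window_bins - 1L) %/% 2L
        bin <- bin_of(st$pos[sub], config$bin_size)
        g2 <- g * g
        grp_of_pair <- rep(seq_along(g), g2)
        within <- sequence(g2) - 1L
        gg <- rep(g, g2)
        li <- within %% gg + 1L
        lj <- within %/% gg + 1L
        base <- rep(cumsum(c(0L, g[-length(g)])), g2)
        i_row <- base + li
        j_row <- base + lj
        same <- st$reference[sub][i_row] == st$reference[sub][j_row] &
          abs(bin[i_row] - bin[j_row]) <= half
        n_pair <- rd$n[sub_read[j_row]]
        excl <- rowsum(as.numeric(same) / n_pair, i_row)
        excl_vec <- numeric(length(sub))
        excl_vec[as.integer(rownames(excl))] <- excl[, 1L]
        w <- w - excl_vec
        w[w < 0 & w > -1e-9] <- 0  # clip float residue
      }
      ends <- cumsum(g)
      starts <- ends - g + 1L
      mx <- vapply(seq_along(g), function(k)
        max(w[starts[k]:ends[k]]), numeric(1))
      mn <- vapply(seq_along(g), function(k)
        min(w[starts[k]:ends[k]]), numeric(1))
      tie <- mx <= 0 | (mx - mn) <= 1e-9 * mx
    }

    # resolve ties: uniform when n <= threshold, suppressed otherwise
    n_todo <- rd$n[todo]
    suppress <- tie & n_todo > config$tie_suppression_threshold
    place_uniform <- tie & !suppress
    if (any(place_uniform))
      w[rep(place_uniform, g)] <- 1
    status[todo[suppress]] <- "T"
    keep <- !suppress
    if (any(keep)) {
      keep_site <- rep(keep, g)
      pick_local <- sample_grouped(w[keep_site], g[keep])
      w_k <- w[keep_site]
      ends_k <- cumsum(g[keep])
      starts_k <- ends_k - g[keep] + 1L
      denom <- vapply(seq_along(ends_k), function(k)
        sum(w_k[starts_k[k]:ends_k[k]]), numeric(1))
      chosen_row[todo[keep]] <- sub[keep_site][pick_local]
      prob_chosen[todo[keep]] <- w_k[pick_local] / denom
    }
  }

  dec <- data.frame(read_id = rd$read_id, n = rd$n, overflow = rd$overflow,
                    status = status,
                    chosen_reference = st$reference[chosen_row],
                    chosen_pos = st$pos[chosen_row],
                    chosen_strand = st$strand[chosen_row],
                    probability = prob_chosen,
                    stringsAsFactors = FALSE)
  structure(list(decisions = dec, sites = st, reads = rd,
                 ref_lengths = aln$ref_lengths, config = config),
            class = "srna_placements")
}
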