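#' Classify placed reads against simulated truth
#'
#' Applies the benchmark's confusion classes: a placed read whose primary
#' site matches the truth exactly on (reference, strand, leftmost position)
#' is a true positive (TP) and a false positive (FP) otherwise; an unplaced
#' read (suppressed, overflow, discarded, or without sites) is a false
#' negative (FN) when at least one valid alignment position exists for it
#' and a true negative (TN) when none does. Alignability is taken from the
#' same aligner run that produced the placements, so an error-bearing read
#' that happens to align elsewhere is scored honestly.
#'
#' @param placements An `srna_placements` from [place_library()].
#' @param truth Truth data frame (or a `sim_library`) with `read_id`,
#'   `true_reference`, `true_start`, `true_strand`.
#' @return The decisions data frame with added columns `outcome` (one of
#'   `"TP"`, `"FP"`, `"TN"`, `"FN"`) and `class` (locus class, when present
#'   in the truth).
#' @export
classify_reads <- function(placements, truth) {
  stopifnot(inherits(placements, "srna_placements"))
  if (inherits(truth, "sim_library")) truth <- truth$truth
  dec <- placements$decisions
  i <- match(dec$read_id, truth$read_id)
  if (anyNA(i))
    stop("read absent from truth table: ", dec$read_id[which(is.na(i))[1]])
  placed <- dec$status == "P"
  correct <- placed &
    dec$chosen_reference == truth$true_reference[i] &
    dec$chosen_pos == truth$true_start[i] &
    dec$chosen_strand == truth$true_strand[i]
  alignable <- dec$n >= 1L | dec$overflow
  dec$outcome <- ifelse(placed, ifelse(correct, "TP", "FP"),
                        ifelse(alignable, "FN", "TN"))
  if (!is.null(truth$class)) dec$class <- truth$class[i]
  dec
}

#' Confusion counts from classified reads
#' @param classified Output of [classify_reads()] (or any data frame with
#'   an `outcome` column).
#' @return Named integer vector with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(classified) {
  out <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  tb <- table(classified$outcome)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Performance metrics from confusion counts
#'
#' Precision = TP/(TP+FP), sensitivity = TP/(TP+FN), F1 their harmonic
#' mean. Two false-negative rates are reported: `fnr` = FN/(FP+TP), the
#' definition used when only alignment yields are observable, and
#' `fnr_standard` = FN/(FN+TP). Metrics with a zero denominator are `NA`
#' (undefined), never 0.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN` (or a classified
#'   data frame, which is tallied first).
#' @return One-row data frame with the counts and derived metrics.
#' @export
compute_metrics <- function(counts) {
  if (is.data.frame(counts)) counts <- confusion_counts(counts)
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  p <- sdiv(tp, tp + fp)
  s <- sdiv(tp, tp + fn)
  f1 <- if (!is.na(p) && !is.na(s) && (p + s) > 0) 2 * p * s / (p + s)
        else NA_real_
  data.frame(TP = tp, FP = fp, TN = tn, FN = fn,
             precision = p, sensitivity = s, f1 = f1,
             fnr = sdiv(fn, fp + tp),
             fnr_standard = sdiv(fn, fn + tp))
}

#' Metrics stratified by MMAP-value
#'
#' Emits one row per scope: `all` (every read), `mmap_only` (reads with at
#' least two candidate positions, overflow included), `per_mmap(n)`
#' (reads with MMAP-value exactly `n`) and `cumulative_le(n)` (MMAP-value
#' at most `n`), for `n` from 1 up to `max_n` (default: the largest
#' observed value).
#'
#' @param classified Output of [classify_reads()].
#' @param max_n Largest MMAP-value to stratify on.
#' @return Data frame of metric rows with `scope` and `n` columns.
#' @export
metrics_by_mmap <- function(classified, max_n = NULL) {
  if (is.null(max_n)) max_n <- max(classified$n, 1L)
  mm <- classified$n >= 2L | classified$overflow
  rows <- list(
    cbind(scope = "all", n = NA_integer_, compute_metrics(classified)),
    cbind(scope = "mmap_only", n = NA_integer_,
          compute_metrics(classified[mm, , drop = FALSE])))
  for (k in seq_len(max_n)) {
    exact <- classified$n == k & !classified$overflow
    cum <- classified$n <= k & !classified$overflow
    rows[[length(rows) + 1L]] <-
      cbind(scope = "per_mmap", n = k,
            compute_metrics(classified[exact, , drop = FALSE]))
    rows[[length(rows) + 1L]] <-
      cbind(scope = "cumulative_le", n = k,
            compute_metrics(classified[cum, , drop = FALSE]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Library retention under MMAP-value cutoffs
#'
#' Fraction of reads whose MMAP-value is between 1 and the cutoff, i.e. the
#' proportion of the library placeable under that reporting cap. Reads with
#' no valid alignment are never retained; overflow reads (true MMAP-value
#' above the cap they were aligned with) count above every cutoff.
#'
#' @param aln An `srna_alignments` object.
#' @param cutoffs Integer vector of MMAP-value cutoffs.
#' @return Data frame with `cutoff` and `retained` (non-decreasing
#'   fractions in \[0,1\]).
#' @export
retention_curve <- function(aln, cutoffs) {
  stopifnot(inherits(aln, "srna_alignments"))
  rd <- aln$reads
  total <- nrow(rd)
  retained <- vapply(cutoffs, function(cut)
    sum(rd$n >= 1L & rd$n <= cut & !rd$overflow) / total, numeric(1))
  data.frame(cutoff = as.integer(cutoffs), retained = retained)
}

#' Strand bias of placed reads
#'
#' Ratio of primary alignments on the top (plus) strand to those on the
#' bottom (minus) strand; `NA` when the denominator is zero or no read was
#' placed.
#'
#' @param placements An `srna_placements` object.
#' @return A single number (or `NA`).
#' @export
strand_bias <- function(placements) {
  stopifnot(inherits(placements, "srna_placements"))
  dec <- placements$decisions
  placed <- dec[dec$status == "P", , drop = FALSE]
  if (nrow(placed) == 0L) return(NA_real_)
  top <- sum(placed$chosen_strand == "+")
  bot <- sum(placed$chosen_strand == "-")
  if (bot == 0L) return(NA_real_)
  top / bot
}

#' Evaluate a placement run against simulated truth
#'
#' Convenience wrapper: classifies reads, tallies the confusion matrix and
#' produces the stratified metrics table, retention curve and strand-bias
#' ratio.
#'
#' @param placements An `srna_placements` object.
#' @param truth Truth table (or `sim_library`).
#' @param max_n Largest MMAP-value for stratified rows.
#' @return List with `classified`, `counts`, `metrics` (from
#'   [metrics_by_mmap()]), `retention` and `strand_bias`.
#' @export
evaluate_placements <- function(placements, truth, max_n = NULL) {
  cl <- classify_reads(placements, truth)
  aln <- structure(list(reads = placements$reads, sites = placements$sites,
                        ref_lengths = placements$ref_lengths),
                   class = "srna_alignments")
  mx <- max(placements$reads$n, 1L)
  list(classified = cl,
       counts = confusion_counts(cl),
       metrics = metrics_by_mmap(cl, max_n),
       retention = retention_curve(aln, cutoffs = seq_len(mx)),
       strand_bias = strand_bias(placements))
}
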