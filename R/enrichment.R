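#' Base-level overlap enrichment of an annotation against interval sets
#'
#' For every (state, label) pair: `fold = (bases of the state overlapping the
#' label / bases of the state) / (bases of the label / annotated genome
#' bases)`. Significance is a two-sided exact binomial test with n = bases
#' of the state, success probability = the label's genome fraction, observed
#' = overlapping bases; p-values are BH-adjusted across all (state, label)
#' pairs of the call (one family per external annotation source). Intervals
#' are clipped to the annotated coordinate space; partially overlapping bins
#' contribute their overlapping bases.
#'
#' @param annotation a [genome_annotation()].
#' @param intervals an [interval_set()] (labels in the `label` column).
#' @return data.frame with state, label, state_bases, overlap_bases,
#'   label_bases, genome_bases, fold, p, q, significant (fold > 1 and
#'   q < 0.05). States with no bins are omitted.
#' @export
overlap_enrichment <- function(annotation, intervals) {
  stopifnot(inherits(annotation, "genome_annotation"))
  intervals <- as.data.frame(intervals)
  k <- annotation$k
  genome_bases <- sum(annotation$bins$end - annotation$bins$start)
  state_bases <- 200 * tabulate(annotation$state, nbins = k)

  labels <- sort(unique(intervals$label))
  rows <- list()
  for (lab in labels) {
    ov <- overlap_bases_by_state(annotation, intervals[intervals$label == lab, ])
    label_bases <- sum(ov)
    if (label_bases == 0)
      stop(sprintf("label '%s' covers 0 bases of the annotated genome", lab))
    pr <- label_bases / genome_bases
    for (s in seq_len(k)) {
      if (state_bases[s] == 0) next
      fold <- (ov[s] / state_bases[s]) / pr
      rows[[length(rows) + 1]] <- data.frame(
        state = s, label = lab, state_bases = state_bases[s],
        overlap_bases = ov[s], label_bases = label_bases,
        genome_bases = genome_bases, fold = fold,
        p = binom_two_sided(round(ov[s]), state_bases[s], pr),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fold > 1 & res$q < 0.05
  res
}

# bases of each state overlapped by a set of intervals (single label)
overlap_bases_by_state <- function(annotation, ints) {
  k <- annotation$k
  ov <- numeric(k)
  bins <- annotation$bins
  for (ch in unique(ints$chrom)) {
    bidx <- which(bins$chrom == ch)
    if (length(bidx) == 0) next
    s0 <- bins$start[bidx[1]]
    n <- length(bidx)
    st <- annotation$state[bidx]
    sub <- ints[ints$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      cs <- max(sub$start[r], s0)
      ce <- min(sub$end[r], s0 + 200 * n)
      if (ce <= cs) next
      i1 <- floor((cs - s0) / 200) + 1
      i2 <- floor((ce - s0 - 1) / 200) + 1
      idx <- i1:i2
      bs <- s0 + 200 * (idx - 1)
      o <- pmin(ce, bs + 200) - pmax(cs, bs)
      add <- rowsum(o, st[idx])
      ov[as.integer(rownames(add))] <- ov[as.integer(rownames(add))] + add[, 1]
    }
  }
  ov
}

# Two-sided exact binomial p: sum of the probabilities of all outcomes at
# most as probable as the observed one (the classical exact two-sided
# definition). Unimodality of the pmf lets the opposite tail be located by
# bisection instead of scanning 0..n, so large base counts stay cheap.
binom_two_sided <- function(x, n, p) {
  if (p >= 1) return(1)
  d0 <- stats::dbinom(x, n, p) * (1 + 1e-7)
  mode <- floor((n + 1) * p)
  if (x == mode || stats::dbinom(mode, n, p) <= d0) return(1)
  if (x < mode) {
    left <- stats::pbinom(x, n, p)
    # smallest y > mode with pmf(y) <= d0 (pmf decreasing right of mode)
    lo <- mode; hi <- n
    if (stats::dbinom(n, n, p) > d0) return(min(1, left))
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (stats::dbinom(mid, n, p) <= d0) hi <- mid else lo <- mid
    }
    min(1, left + stats::pbinom(hi - 1, n, p, lower.tail = FALSE))
  } else {
    right <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
    if (stats::dbinom(0, n, p) > d0) return(min(1, right))
    lo <- 0; hi <- mode
    # largest y < mode with pmf(y) <= d0 (pmf increasing left of mode)
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (stats::dbinom(mid, n, p) <= d0) lo <- mid else hi <- mid
    }
    if (stats::dbinom(lo, n, p) > d0) return(min(1, right))
    min(1, right + stats::pbinom(lo, n, p))
  }
}

#' Label states by their most enriched reference annotation
#'
#' For each state, among reference labels with fold > 1 and BH q < 0.05,
#' returns the label with the highest fold (ties broken lexicographically);
#' states with no significant label are `"unlabeled"`.
#'
#' @param annotation a [genome_annotation()].
#' @param reference a labeled [interval_set()] (e.g. reference chromatin
#'   states).
#' @return character vector, one label per state, with the full enrichment
#'   table as attribute `"enrichment"`.
#' @export
label_states <- function(annotation, reference) {
  enr <- overlap_enrichment(annotation, reference)
  out <- rep("unlabeled", annotation$k)
  for (s in seq_len(annotation$k)) {
    cand <- enr[enr$state == s & enr$significant, , drop = FALSE]
    if (nrow(cand) == 0) next
    cand <- cand[order(-cand$fold, cand$label), , drop = FALSE]
    out[s] <- cand$label[1]
  }
  attr(out, "enrichment") <- enr
  out
}

#' Promoter intervals as TSS flanks
#'
#' Builds `[pos - flank, pos + flank)` intervals around transcription start
#' sites, clipped to chromosome bounds, with overlapping flanks merged.
#'
#' @param tss_table data.frame with chrom, pos, strand.
#' @param flank flank size in bases (default 2000, i.e. TSS +/- 2 kb).
#' @param chrom_lengths named vector of chromosome lengths for clipping.
#' @return an [interval_set()] labeled `"promoter"`.
#' @export
tss_flank_intervals <- function(tss_table, flank = 2000,
                                chrom_lengths = NULL) {
  tss_table <- as.data.frame(tss_table)
  stopifnot(all(c("chrom", "pos") %in% names(tss_table)))
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[tss_table$chrom]
    if (anyNA(len)) stop("TSS on a chromosome without a length")
    if (any(tss_table$pos > len)) stop("TSS beyond chromosome length")
  }
  start <- pmax(tss_table$pos - flank, 0)
  end <- tss_table$pos + flank
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[tss_table$chrom])
  interval_set(data.frame(chrom = tss_table$chrom, start = start, end = end,
                          label = "promoter"))
}

#' Fisher's exact overlap of two feature sets
#'
#' 2x2 membership table of two sets within a universe; two-sided Fisher's
#' exact p and fold enrichment = observed overlap / expected
#' (`|A| |B| / |U|`).
#'
#' @param set_a,set_b vectors of feature ids; must be subsets of `universe`.
#' @param universe vector of all feature ids.
#' @return list with `overlap`, `expected`, `fold`, `odds_ratio`, `p`, and
#'   the 2x2 `table`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  obs <- sum(in_a & in_b)
  expected <- length(set_a) * length(set_b) / length(universe)
  list(overlap = obs, expected = expected,
       fold = if (expected > 0) obs / expected else NA_real_,
       odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
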