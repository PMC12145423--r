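#' Binned track matrix
#'
#' Container for multi-individual signal quantified in 200 bp non-overlapping
#' genomic bins. Rows are bins, columns are tracks, where a track is one
#' (individual, mark) ChIP-seq data set. This is the common currency of the
#' preprocessing stages: raw counts, quantile-normalized counts and
#' covariate-corrected signal are all `binned_track_matrix` objects.
#'
#' @param values numeric matrix, bins x tracks, non-negative.
#' @param bins data.frame with columns `chrom`, `start`, `end`; bins must be
#'   200 bp wide, sorted by (chrom, start) and unique.
#' @param tracks data.frame with columns `individual` and `mark`, one row per
#'   column of `values`.
#' @return an object of class `binned_track_matrix`.
#' @export
binned_track_matrix <- function(values, bins, tracks) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (any(values < 0)) stop("signal values must be non-negative")
  bins <- as.data.frame(bins)
  if (!all(c("chrom", "start", "end") %in% names(bins)))
    stop("bins must have columns chrom, start, end")
  if (nrow(bins) != nrow(values))
    stop("bins and values disagree on the number of bins")
  if (any(bins$end - bins$start != 200L))
    stop("bins must be 200 bp wide")
  ord <- order(bins$chrom, bins$start)
  if (any(ord != seq_len(nrow(bins))))
    stop("bins must be sorted by (chrom, start)")
  if (anyDuplicated(paste(bins$chrom, bins$start)))
    stop("duplicate bins")
  tracks <- as.data.frame(tracks)
  if (!all(c("individual", "mark") %in% names(tracks)))
    stop("tracks must have columns individual, mark")
  if (nrow(tracks) != ncol(values))
    stop("tracks and values disagree on the number of tracks")
  tracks$track_id <- paste(tracks$individual, tracks$mark, sep = "_")
  colnames(values) <- tracks$track_id
  structure(list(values = values, bins = bins, tracks = tracks),
            class = "binned_track_matrix")
}

#' @export
print.binned_track_matrix <- function(x, ...) {
  cat(sprintf("binned_track_matrix: %d bins x %d tracks (%d individuals, marks: %s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$tracks$individual)),
              paste(unique(x$tracks$mark), collapse = ", ")))
  invisible(x)
}

#' @export
dim.binned_track_matrix <- function(x) dim(x$values)

#' Binary presence/absence call matrix
#'
#' Result of Poisson-background binarization: per bin and track, 1 if the
#' corrected signal exceeds the track's Poisson tail threshold.
#'
#' @param calls integer/numeric matrix in {0,1}, bins x tracks.
#' @param bins,tracks bin and track metadata as in [binned_track_matrix()].
#' @param thresholds optional per-track integer thresholds used for the calls.
#' @return an object of class `binary_call_matrix`.
#' @export
binary_call_matrix <- function(calls, bins, tracks, thresholds = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0, 1))) stop("calls must be in {0, 1}")
  storage.mode(calls) <- "integer"
  src <- binned_track_matrix(calls, bins, tracks)
  structure(list(calls = src$values, bins = src$bins, tracks = src$tracks,
                 thresholds = thresholds),
            class = "binary_call_matrix")
}

#' @export
print.binary_call_matrix <- function(x, ...) {
  cat(sprintf("binary_call_matrix: %d bins x %d tracks, overall call rate %.3f\n",
              nrow(x$calls), ncol(x$calls), mean(x$calls)))
  invisible(x)
}

#' Genome annotation: one state per 200 bp bin
#'
#' A single universal annotation shared by all individuals: per bin, the id
#' of the global pattern (HMM state) assigned to it.
#'
#' @param state integer vector of state ids in `1..k`, one per bin.
#' @param bins bin metadata data.frame (chrom, start, end).
#' @param k number of states of the generating model.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(state, bins, k) {
  state <- as.integer(state)
  bins <- as.data.frame(bins)
  stopifnot(length(state) == nrow(bins), all(state >= 1L), all(state <= k))
  structure(list(state = state, bins = bins, k = as.integer(k)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d bins, %d states, %d chromosome(s)\n",
              length(x$state), x$k, length(unique(x$bins$chrom))))
  invisible(x)
}

#' Export a genome annotation as BED4
#'
#' Writes 0-based half-open intervals with state labels `GP<id>`, merging
#' adjacent bins carrying the same state.
#'
#' @param x a [genome_annotation()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_annotation_bed <- function(x, path) {
  stopifnot(inherits(x, "genome_annotation"))
  b <- x$bins
  new_run <- c(TRUE, x$state[-1] != x$state[-length(x$state)] |
                 b$chrom[-1] != b$chrom[-nrow(b)] |
                 b$start[-1] != b$end[-nrow(b)])
  run_id <- cumsum(new_run)
  df <- data.frame(
    chrom = tapply(b$chrom, run_id, `[`, 1),
    start = tapply(b$start, run_id, min),
    end   = tapply(b$end, run_id, max),
    name  = paste0("GP", tapply(x$state, run_id, `[`, 1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file into an interval set
#'
#' @param path BED file path (0-based half-open; optional 4th label column).
#' @return data.frame with columns chrom, start, end and label (label `"."`
#'   when the file has no 4th column), class `interval_set`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    label = if (ncol(df) >= 4) as.character(df[[4]]) else ".")
  interval_set(out)
}

#' Construct an interval set
#'
#' Normalizes a table of genomic intervals: validates start < end and merges
#' overlapping intervals within each label.
#'
#' @param df data.frame with chrom, start, end and optionally label.
#' @return data.frame of class `interval_set`, merged within label.
#' @export
interval_set <- function(df) {
  df <- as.data.frame(df)
  if (is.null(df$label)) df$label <- "."
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  merged <- do.call(rbind, lapply(split(df, list(df$chrom, df$label), drop = TRUE),
                                  merge_intervals_one))
  merged <- merged[order(merged$label, merged$chrom, merged$start), ]
  rownames(merged) <- NULL
  class(merged) <- c("interval_set", "data.frame")
  merged
}

merge_intervals_one <- function(d) {
  d <- d[order(d$start), ]
  if (nrow(d) > 1) {
    keep_start <- d$start[1]
    out_s <- numeric(0); out_e <- numeric(0)
    cur_s <- d$start[1]; cur_e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur_e) {
        cur_e <- max(cur_e, d$end[i])
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
    d <- data.frame(chrom = d$chrom[1], start = out_s, end = out_e,
                    label = d$label[1])
  }
  d[, c("chrom", "start", "end", "label")]
}
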