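#' Write / read a binned track matrix as TSV
#'
#' Column header is the track ids (`individual_mark`); the first three
#' columns are the bin coordinates.
#'
#' @param x a [binned_track_matrix()].
#' @param path file path.
#' @return the path (writer) / a [binned_track_matrix()] (reader).
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "binned_track_matrix"))
  df <- cbind(x$bins[, c("chrom", "start", "end")], as.data.frame(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- names(df)[-(1:3)]
  parts <- regmatches(ids, regexpr("_", ids), invert = TRUE)
  tracks <- data.frame(individual = vapply(parts, `[`, "", 1),
                       mark = vapply(parts, `[`, "", 2))
  binned_track_matrix(as.matrix(df[, -(1:3), drop = FALSE]),
                      df[, 1:3], tracks)
}

#' Write binary calls per chromosome with a two-line header
#'
#' One file per chromosome (`<prefix>_<chrom>_binary.txt`): line 1 is
#' `<cell>\t<chrom>`, line 2 the track ids, then one 0/1 row per 200 bp bin —
#' the conventional input layout of chromatin-segmentation tools.
#'
#' @param calls a [binary_call_matrix()].
#' @param prefix output path prefix.
#' @param cell cell/data-set label for the header.
#' @return the written paths, invisibly.
#' @export
write_binary_calls <- function(calls, prefix, cell = "synthetic") {
  stopifnot(inherits(calls, "binary_call_matrix"))
  paths <- character(0)
  for (ch in unique(calls$bins$chrom)) {
    idx <- calls$bins$chrom == ch
    path <- sprintf("%s_%s_binary.txt", prefix, ch)
    con <- file(path, "w")
    writeLines(c(paste(cell, ch, sep = "\t"),
                 paste(calls$tracks$track_id, collapse = "\t")), con)
    utils::write.table(calls$calls[idx, , drop = FALSE], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the true state path as BED3 + state
#'
#' @param truth a [simulate_truth()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  df <- cbind(truth$bins[, c("chrom", "start", "end")],
              state = truth$state_path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simple keyed table as TSV
#'
#' Used for covariates, expression matrices, TSS tables and association
#' results.
#'
#' @param x data.frame or matrix.
#' @param path output path.
#' @param row_names write row names as a first column (default TRUE for
#'   matrices with row names).
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path, row_names = !is.null(rownames(x)) &&
                        !identical(rownames(x), as.character(seq_len(nrow(x))))) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}

#' Write a synthetic configuration as YAML
#'
#' @param config a [synth_config()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  x <- unclass(config)
  if (is.matrix(x$emission_arch))
    x$emission_arch <- list(matrix = apply(x$emission_arch, 1, as.numeric,
                                           simplify = FALSE))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a synthetic configuration from YAML
#'
#' @param path YAML path written by [write_config_yaml()] or hand-authored
#'   with the same fields.
#' @return a [synth_config()].
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$emission_arch$matrix))
    x$emission_arch <- do.call(rbind, x$emission_arch$matrix)
  args <- x[intersect(names(x), names(formals(synth_config)))]
  do.call(synth_config, args)
}
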