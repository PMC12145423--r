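#' Median mark-pair Spearman correlation of emission parameters
#'
#' Internal-consistency diagnostic: marks that co-occur in the genome should
#' have correlated emission parameters across individuals within each global
#' pattern, even though the model is trained agnostic to mark labels. For
#' each pair of marks and each state, the Spearman correlation across
#' individuals between the two marks' emission sub-vectors is computed; each
#' pair is summarized by the median over states.
#'
#' @param model a `gp_hmm` (or a bare emission matrix via `tracks`).
#' @param tracks track metadata when `model` is a matrix.
#' @return data.frame with columns `mark_a`, `mark_b`, `median_rho`, and the
#'   per-state correlations as attribute `"per_state"`.
#' @export
mark_pair_correlation <- function(model, tracks = NULL) {
  em <- if (inherits(model, "gp_hmm")) model$emission else as.matrix(model)
  if (is.null(tracks)) tracks <- model$tracks
  marks <- unique(tracks$mark)
  if (length(marks) < 2) stop("need >= 2 marks")
  blocks <- lapply(marks, function(m) {
    cols <- which(tracks$mark == m)
    if (length(cols) < 3)
      stop("each mark needs >= 3 individuals for Spearman correlation")
    # align individuals so every block is in the same individual order
    cols[order(tracks$individual[cols])]
  })
  names(blocks) <- marks
  pairs <- utils::combn(marks, 2)
  per_state <- matrix(NA_real_, nrow(em), ncol(pairs))
  out <- data.frame(mark_a = pairs[1, ], mark_b = pairs[2, ],
                    median_rho = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    a <- blocks[[pairs[1, p]]]; b <- blocks[[pairs[2, p]]]
    for (s in seq_len(nrow(em)))
      per_state[s, p] <- stats::cor(em[s, a], em[s, b], method = "spearman")
    out$median_rho[p] <- stats::median(per_state[, p])
  }
  attr(out, "per_state") <- per_state
  out
}

#' Greedily match states between two models
#'
#' Repeatedly pairs the two unmatched states (one from each model) with the
#' highest Spearman correlation between their emission vectors, until one
#' model runs out of states. Deterministic tie-break: smallest
#' (state_A, state_B). Used to compare models trained on different genome
#' subsets or different seeds, where state labels are arbitrary.
#'
#' @param model_a,model_b `gp_hmm` objects or bare emission matrices sharing
#'   track ordering.
#' @return list with `pairs` (data.frame state_a, state_b, rho, in matching
#'   order), `median_rho`, and `unmatched_a`/`unmatched_b` state ids when the
#'   models differ in k.
#' @export
greedy_match_states <- function(model_a, model_b) {
  ea <- if (inherits(model_a, "gp_hmm")) model_a$emission else as.matrix(model_a)
  eb <- if (inherits(model_b, "gp_hmm")) model_b$emission else as.matrix(model_b)
  if (ncol(ea) != ncol(eb))
    stop("models do not share track ordering")
  if (inherits(model_a, "gp_hmm") && inherits(model_b, "gp_hmm") &&
      !identical(model_a$tracks$track_id, model_b$tracks$track_id))
    stop("models do not share track ordering")
  rho <- stats::cor(t(ea), t(eb), method = "spearman")
  ka <- nrow(ea); kb <- nrow(eb)
  free_a <- rep(TRUE, ka); free_b <- rep(TRUE, kb)
  pairs <- data.frame(state_a = integer(0), state_b = integer(0),
                      rho = numeric(0))
  for (step in seq_len(min(ka, kb))) {
    sub <- rho
    sub[!free_a, ] <- -Inf
    sub[, !free_b] <- -Inf
    best <- max(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    pairs <- rbind(pairs, data.frame(state_a = hit[[1]], state_b = hit[[2]],
                                     rho = best))
    free_a[hit[[1]]] <- FALSE
    free_b[hit[[2]]] <- FALSE
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, median_rho = stats::median(pairs$rho),
       unmatched_a = which(free_a), unmatched_b = which(free_b))
}

#' Classify states as singleton or nonsingleton
#'
#' A singleton state has exactly one individual with emission parameter
#' strictly greater than `threshold` — i.e., the "pattern" is one
#' individual's idiosyncratic signal. Every other state is nonsingleton,
#' including states where no individual exceeds the threshold. Replication
#' analyses restrict to nonsingleton states to boost power (analogous to
#' dropping low-MAF variants).
#'
#' @param model a `gp_hmm` or emission matrix.
#' @param threshold emission cut-off (default 0.5; strict `>`).
#' @param mark for multi-mark models, the mark whose emission block to use.
#' @param tracks track metadata when `model` is a matrix.
#' @return character vector (length k) of `"singleton"`/`"nonsingleton"`.
#' @export
classify_singletons <- function(model, threshold = 0.5, mark = NULL,
                                tracks = NULL) {
  em <- if (inherits(model, "gp_hmm")) model$emission else as.matrix(model)
  if (is.null(tracks) && inherits(model, "gp_hmm")) tracks <- model$tracks
  if (!is.null(tracks)) {
    marks <- unique(tracks$mark)
    if (length(marks) > 1) {
      if (is.null(mark))
        stop("multi-mark model: specify which mark's emission block to use")
      em <- em[, tracks$mark == mark, drop = FALSE]
    }
  }
  n_high <- rowSums(em > threshold)
  ifelse(n_high == 1, "singleton", "nonsingleton")
}
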