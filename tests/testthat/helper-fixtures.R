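# Shared fixtures and independent oracles, built in code at test time.

# small binned track matrix with given values (bins x tracks), one mark
make_btm <- function(values, marks = "H3K27ac", chrom = "chr1") {
  values <- as.matrix(values)
  n <- nrow(values)
  n_ind <- ncol(values) / length(marks)
  bins <- data.frame(chrom = chrom, start = 200 * (seq_len(n) - 1),
                     end = 200 * seq_len(n))
  tracks <- data.frame(individual = rep(sprintf("ind%03d", seq_len(n_ind)),
                                        times = length(marks)),
                       mark = rep(marks, each = n_ind))
  binned_track_matrix(values, bins, tracks)
}

make_calls <- function(calls, marks = "H3K27ac", chrom = "chr1") {
  b <- make_btm(calls, marks, chrom)
  binary_call_matrix(b$values, b$bins, b$tracks[, c("individual", "mark")])
}

# hand-built HMM (no fitting) for decode/posterior tests
make_model <- function(emission, transition = NULL, initial = NULL,
                       marks = "H3K27ac") {
  k <- nrow(emission)
  n_ind <- ncol(emission) / length(marks)
  tracks <- data.frame(individual = rep(sprintf("ind%03d", seq_len(n_ind)),
                                        times = length(marks)),
                       mark = rep(marks, each = n_ind))
  tracks$track_id <- paste(tracks$individual, tracks$mark, sep = "_")
  colnames(emission) <- tracks$track_id
  if (is.null(transition)) transition <- matrix(1 / k, k, k)
  if (is.null(initial)) initial <- rep(1 / k, k)
  structure(list(k = k, initial = initial, transition = transition,
                 emission = emission, loglik = NA_real_, trace = NA_real_,
                 iterations = 0L, converged = TRUE, tracks = tracks,
                 seed = 0L),
            class = "gp_hmm")
}

# Independent oracle: exhaustive path enumeration for HMM likelihood and
# posteriors (Bernoulli product emissions). y: T x D calls.
enum_hmm <- function(y, emission, transition, initial) {
  Tn <- nrow(y); k <- nrow(emission)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), Tn)))
  obs_lik <- function(s, t)
    prod(emission[s, ]^y[t, ] * (1 - emission[s, ])^(1 - y[t, ]))
  pw <- apply(paths, 1, function(path) {
    w <- initial[path[1]] * obs_lik(path[1], 1)
    for (t in seq_len(Tn - 1))
      w <- w * transition[path[t], path[t + 1]] * obs_lik(path[t + 1], t + 1)
    w
  })
  total <- sum(pw)
  post <- matrix(0, Tn, k)
  for (t in seq_len(Tn))
    for (s in seq_len(k))
      post[t, s] <- sum(pw[paths[, t] == s]) / total
  xi <- matrix(0, k, k)
  for (t in seq_len(Tn - 1))
    for (i in seq_len(k))
      for (j in seq_len(k))
        xi[i, j] <- xi[i, j] +
          sum(pw[paths[, t] == i & paths[, t + 1] == j]) / total
  list(loglik = log(total), posterior = post, xi = xi)
}

# one-active-state-per-individual architecture: sparse per-track presence,
# the regime in which Poisson-background binarization is calibrated
sparse_arch <- function(k, n_individuals, marks = "H3K27ac", p_on = 0.9,
                        p_off = 0.01) {
  acts <- lapply(seq_len(k), function(s)
    which((seq_len(n_individuals) - 1) %% k + 1 == s))
  emission_architecture(k, n_individuals, marks, active_sets = acts,
                        p_on = p_on, p_off = p_off)
}

# match fitted states to truth and return relabeling vector + max error
match_to_truth <- function(fit, truth) {
  m <- greedy_match_states(fit$emission, truth$true_emissions)
  perm <- integer(fit$k)
  perm[m$pairs$state_a] <- m$pairs$state_b
  list(perm = perm,
       max_err = max(abs(fit$emission[m$pairs$state_a, , drop = FALSE] -
                         truth$true_emissions[m$pairs$state_b, , drop = FALSE])),
       pairs = m$pairs)
}
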