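#' Fit a stacked multivariate-Bernoulli hidden Markov model
#'
#' Learns recurring cross-individual patterns ("global patterns") from
#' binarized histone-modification tracks. Every (individual, mark) data set
#' is one observation dimension of a single HMM over 200 bp genomic bins;
#' given the hidden state, tracks are independent Bernoulli variables, so
#' the emission matrix row of a state is its global pattern: the probability
#' of observing a presence call in each track. Chromosomes are treated as
#' independent sequences sharing parameters. Training is Baum-Welch
#' (EM with scaled forward-backward); the log-likelihood is non-decreasing
#' across iterations.
#'
#' Initialization is seeded: emission rows start at k-means centers of the
#' call vectors mapped into \[0.2, 0.8\] (`init = "kmeans"`, the default) or
#' uniform draws from \[0.2, 0.8\] (`init = "random"`); initial and
#' transition distributions are uniform with Dirichlet jitter. With
#' `restarts > 1` each restart re-seeds the initialization and the fit with
#' the best final log-likelihood is kept.
#'
#' @param calls a [binary_call_matrix()].
#' @param k number of hidden states (global patterns).
#' @param seed integer seed controlling initialization (restart `r` uses
#'   `seed + r - 1`).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change for convergence.
#' @param restarts number of random restarts.
#' @param init initialization scheme: `"kmeans"` (default) or `"random"`.
#' @return an object of class `gp_hmm` with components `k`, `tracks`,
#'   `initial`, `transition`, `emission` (`k x D`), `loglik`, `trace`
#'   (per-iteration log-likelihood), `iterations`, `converged`, `seed`.
#' @seealso [gp_posterior()], [gp_annotate()], [gp_subset_decode()]
#' @export
gp_fit <- function(calls, k, seed = 1L, max_iter = 200L, tol = 1e-4,
                   restarts = 1L, init = c("kmeans", "random")) {
  init <- match.arg(init)
  stopifnot(inherits(calls, "binary_call_matrix"), k >= 1)
  y <- calls$calls
  storage.mode(y) <- "double"
  if (nrow(y) == 0) stop("empty call matrix")
  if (k > nrow(y)) stop("k exceeds the number of bins")
  chrom_idx <- split(seq_len(nrow(y)), calls$bins$chrom)

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- gp_em(y, chrom_idx, k, seed = seed + r - 1L,
                 max_iter = max_iter, tol = tol,
                 init = init)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (k > 1 && anyDuplicated(round(best$emission, 6)))
    warning("duplicate states in the fitted model (identical emission rows)")
  structure(c(best, list(tracks = calls$tracks, seed = as.integer(seed))),
            class = "gp_hmm")
}

# log observation likelihood per (bin, state): product of Bernoulli factors
emission_loglik <- function(y, emission) {
  l1 <- log(emission)
  l0 <- log1p(-emission)
  lb <- y %*% t(l1 - l0)
  sweep(lb, 2, rowSums(l0), `+`)
}

gp_em <- function(y, chrom_idx, k, seed, max_iter, tol,
                  init = "kmeans") {
  eps <- 1e-6
  d <- ncol(y)
  set.seed(seed)
  emission <- NULL
  if (init == "kmeans" && k > 1) {
    # seed emission rows from k-means centers of the call vectors, mapped
    # into [0.2, 0.8]: starts each state near a distinct occupied corner of
    # the hypercube, which reaches the dominant likelihood basin far more
    # reliably than uniform draws
    km <- tryCatch(
      suppressWarnings(stats::kmeans(y, centers = k, nstart = 5,
                                     iter.max = 50)),
      error = function(e) NULL)
    if (!is.null(km)) emission <- 0.2 + 0.6 * km$centers
  }
  if (is.null(emission))
    emission <- matrix(stats::runif(k * d, 0.2, 0.8), nrow = k)
  initial <- as.numeric(stats::rgamma(k, 100)); initial <- initial / sum(initial)
  transition <- matrix(stats::rgamma(k * k, 100), nrow = k)
  transition <- transition / rowSums(transition)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    lb <- emission_loglik(y, emission)
    ll <- 0
    xi <- matrix(0, k, k)
    first <- numeric(k)
    gamma <- matrix(0, nrow(y), k)
    for (idx in chrom_idx) {
      fb <- .fb_chain(lb[idx, , drop = FALSE], initial, transition)
      ll <- ll + fb$loglik
      xi <- xi + fb$xi
      first <- first + fb$gamma[1, ]
      gamma[idx, ] <- fb$gamma
    }
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[iter - 1]) < tol * abs(ll)) {
      converged <- TRUE
      break
    }
    # M-step
    initial <- first / sum(first)
    rs <- rowSums(xi)
    for (i in seq_len(k))
      transition[i, ] <- if (rs[i] > 0) xi[i, ] / rs[i] else rep(1 / k, k)
    occ <- colSums(gamma)
    emission <- (t(gamma) %*% y) / occ
    emission[occ == 0, ] <- 0.5
    emission <- pmin(pmax(emission, eps), 1 - eps)
  }
  colnames(emission) <- colnames(y)
  list(k = as.integer(k), initial = initial, transition = transition,
       emission = emission, loglik = trace[length(trace)], trace = trace,
       iterations = iter, converged = converged)
}

check_tracks <- function(model, calls) {
  if (ncol(calls$calls) != ncol(model$emission) ||
      !identical(calls$tracks$track_id, model$tracks$track_id))
    stop("model tracks do not match the call matrix tracks")
}

#' Posterior state probabilities
#'
#' Forward-backward posteriors of each global pattern at each bin; rows sum
#' to one.
#'
#' @param model a fitted [gp_fit()] model.
#' @param calls a [binary_call_matrix()] with the model's tracks.
#' @return bins x k matrix of posterior probabilities.
#' @export
gp_posterior <- function(model, calls) {
  stopifnot(inherits(model, "gp_hmm"))
  check_tracks(model, calls)
  y <- calls$calls; storage.mode(y) <- "double"
  lb <- emission_loglik(y, model$emission)
  post <- matrix(0, nrow(y), model$k)
  for (idx in split(seq_len(nrow(y)), calls$bins$chrom))
    post[idx, ] <- .fb_chain(lb[idx, , drop = FALSE], model$initial,
                             model$transition)$gamma
  post
}

#' Data log-likelihood under a fitted model
#'
#' @inheritParams gp_posterior
#' @return scalar log-likelihood.
#' @export
gp_loglik <- function(model, calls) {
  stopifnot(inherits(model, "gp_hmm"))
  check_tracks(model, calls)
  y <- calls$calls; storage.mode(y) <- "double"
  lb <- emission_loglik(y, model$emission)
  ll <- 0
  for (idx in split(seq_len(nrow(y)), calls$bins$chrom))
    ll <- ll + .fb_chain(lb[idx, , drop = FALSE], model$initial,
                         model$transition)$loglik
  ll
}

#' Annotate the genome with global patterns
#'
#' Assigns every 200 bp bin the most likely hidden state (posterior argmax;
#' ties broken by the smallest state id), producing one universal annotation
#' shared by all individuals.
#'
#' @inheritParams gp_posterior
#' @return a [genome_annotation()].
#' @export
gp_annotate <- function(model, calls) {
  post <- gp_posterior(model, calls)
  genome_annotation(.argmax_rows(post), calls$bins, model$k)
}

#' Decode with a subset of tracks and score annotation recovery
#'
#' Re-annotates the genome using only `track_subset` (the dropped tracks'
#' Bernoulli factors are marginalized out of the observation likelihood) and
#' compares against the full-track annotation. `confusion[i, j]` is the
#' fraction of bins annotated `i` by the full set that the subset annotates
#' `j`; rows sum to 1 (rows of states absent from the full annotation are
#' `NA`). The mean diagonal summarizes how much of the annotation the subset
#' recovers.
#'
#' @inheritParams gp_posterior
#' @param track_subset integer indices or track ids (`individual_mark`).
#' @return list with `annotation` (the subset-decoded [genome_annotation()]),
#'   `confusion` (k x k matrix) and `recovery` (mean diagonal over states
#'   present in the full annotation).
#' @export
gp_subset_decode <- function(model, calls, track_subset) {
  stopifnot(inherits(model, "gp_hmm"))
  check_tracks(model, calls)
  if (is.character(track_subset))
    track_subset <- match(track_subset, model$tracks$track_id)
  track_subset <- unique(as.integer(track_subset))
  if (length(track_subset) == 0 || anyNA(track_subset) ||
      any(track_subset < 1) || any(track_subset > ncol(model$emission)))
    stop("track_subset must be a nonempty subset of the model's tracks")

  full <- gp_annotate(model, calls)
  y <- calls$calls[, track_subset, drop = FALSE]
  storage.mode(y) <- "double"
  lb <- emission_loglik(y, model$emission[, track_subset, drop = FALSE])
  post <- matrix(0, nrow(y), model$k)
  for (idx in split(seq_len(nrow(y)), calls$bins$chrom))
    post[idx, ] <- .fb_chain(lb[idx, , drop = FALSE], model$initial,
                             model$transition)$gamma
  sub_state <- .argmax_rows(post)

  k <- model$k
  conf <- matrix(NA_real_, k, k)
  tab <- table(factor(full$state, levels = 1:k),
               factor(sub_state, levels = 1:k))
  cover <- rowSums(tab)
  for (i in seq_len(k)) if (cover[i] > 0) conf[i, ] <- tab[i, ] / cover[i]
  list(annotation = genome_annotation(sub_state, calls$bins, k),
       confusion = conf,
       recovery = mean(diag(conf)[cover > 0]))
}

#' @export
print.gp_hmm <- function(x, ...) {
  cat(sprintf("gp_hmm: %d global patterns over %d tracks (%d marks); logLik %.2f after %d iterations%s\n",
              x$k, ncol(x$emission), length(unique(x$tracks$mark)),
              x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.gp_hmm <- function(object, ...) {
  occ <- rowSums(object$emission > 0.5)
  cat(sprintf("Stacked Bernoulli HMM with %d states, %d tracks\n",
              object$k, ncol(object$emission)))
  cat(sprintf("  final logLik: %.2f (%d iterations, converged: %s)\n",
              object$loglik, object$iterations, object$converged))
  cat(sprintf("  mean self-transition: %.3f\n", mean(diag(object$transition))))
  cat("  per-state tracks with emission > 0.5:\n")
  print(stats::setNames(occ, paste0("GP", seq_len(object$k))))
  invisible(object)
}

#' @export
coef.gp_hmm <- function(object, ...) object$emission

#' @export
logLik.gp_hmm <- function(object, ...) {
  structure(object$loglik, df = with(object,
    k - 1 + k * (k - 1) + length(emission)), class = "logLik")
}

#' @export
predict.gp_hmm <- function(object, newdata,
                           type = c("states", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "posterior") gp_posterior(object, newdata)
  else gp_annotate(object, newdata)
}

#' Simulate binarized tracks from a fitted model
#'
#' Draws a state path from the model's Markov chain and presence calls from
#' its per-state Bernoulli emissions; useful for parametric-bootstrap checks.
#'
#' @param object a `gp_hmm`.
#' @param nsim number of bins to simulate.
#' @param seed RNG seed.
#' @param chrom chromosome name for the synthetic bins.
#' @param ... unused.
#' @return a [binary_call_matrix()] with attribute `"states"`.
#' @export
simulate.gp_hmm <- function(object, nsim = 1000, seed = NULL, chrom = "chr1",
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- object$k
  state <- integer(nsim)
  state[1] <- sample.int(k, 1, prob = object$initial)
  for (t in seq_len(nsim - 1))
    state[t + 1] <- sample.int(k, 1, prob = object$transition[state[t], ])
  p <- object$emission[state, , drop = FALSE]
  callsm <- matrix((stats::runif(length(p)) < p) * 1L, nrow = nsim)
  start <- 200 * (seq_len(nsim) - 1)
  out <- binary_call_matrix(callsm,
                            data.frame(chrom = chrom, start = start,
                                       end = start + 200),
                            object$tracks[, c("individual", "mark")])
  attr(out, "states") <- state
  out
}

#' Heatmap of the emission (global pattern) matrix
#'
#' @param x a `gp_hmm`.
#' @param ... passed to [graphics::image()].
#' @export
plot.gp_hmm <- function(x, ...) {
  graphics::image(t(x$emission), axes = FALSE,
                  xlab = "track (individual x mark)",
                  ylab = "global pattern",
                  main = sprintf("%d-state emission matrix", x$k), ...)
  graphics::axis(2, at = seq(0, 1, length.out = x$k),
                 labels = paste0("GP", seq_len(x$k)), las = 1, cex.axis = 0.6)
  invisible(x)
}

#' Serialize / read a fitted model as TSV + JSON sidecar
#'
#' Writes `<prefix>_emissions.tsv` (k x D with track-id header),
#' `<prefix>_transitions.tsv`, `<prefix>_initial.tsv` and `<prefix>_model.json`
#' (k, tracks, seed, iterations, final log-likelihood).
#'
#' @param model a `gp_hmm`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_model <- function(model, prefix) {
  stopifnot(inherits(model, "gp_hmm"))
  utils::write.table(model$emission, paste0(prefix, "_emissions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(model$transition, paste0(prefix, "_transitions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(model$initial, paste0(prefix, "_initial.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(k = model$k, tracks = model$tracks$track_id, seed = model$seed,
         iterations = model$iterations, loglik = model$loglik,
         converged = model$converged),
    paste0(prefix, "_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_model
#' @param tracks track metadata data.frame (individual, mark) matching the
#'   serialized emission columns.
#' @export
read_model <- function(prefix, tracks) {
  em <- as.matrix(utils::read.table(paste0(prefix, "_emissions.tsv"),
                                    sep = "\t", header = TRUE,
                                    check.names = FALSE))
  tr <- as.matrix(utils::read.table(paste0(prefix, "_transitions.tsv"),
                                    sep = "\t", header = FALSE))
  dimnames(tr) <- NULL
  init <- as.numeric(utils::read.table(paste0(prefix, "_initial.tsv"))[[1]])
  meta <- jsonlite::read_json(paste0(prefix, "_model.json"),
                              simplifyVector = TRUE)
  tracks <- as.data.frame(tracks)
  tracks$track_id <- paste(tracks$individual, tracks$mark, sep = "_")
  structure(list(k = as.integer(meta$k), initial = init, transition = tr,
                 emission = em, loglik = meta$loglik,
                 trace = meta$loglik, iterations = meta$iterations,
                 converged = isTRUE(meta$converged), tracks = tracks,
                 seed = meta$seed),
            class = "gp_hmm")
}
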