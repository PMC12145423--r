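#' Mann-Whitney U association of global patterns with a binary phenotype
#'
#' Per state, compares the per-individual emission parameters between the
#' two label groups with a two-sided Mann-Whitney U test. Groups of at
#' least 8 on both sides use the tie-corrected normal approximation;
#' smaller designs use exact enumeration of all label assignments (the U
#' distribution over all ways to choose the case set from the observed
#' values, two-sided by distance from the mean).
#'
#' @param model a fitted `gp_hmm`.
#' @param mark which mark's emission block to use (single-mark models may
#'   omit it).
#' @param labels 0/1 vector, either named by individual id or in the order
#'   of the model's individuals; group 1 is "case".
#' @return data.frame with state, U (cases' U statistic), p.
#' @export
mwu_phenotype <- function(model, mark = NULL, labels) {
  em <- emission_block(model, mark)
  labels <- align_labels(labels, colnames(em))
  if (length(unique(labels)) < 2) stop("both label groups must be nonempty")
  mw <- mwu_prepare(em, labels)
  p <- mwu_pvalues(mw, as.numeric(labels == 1))
  data.frame(state = seq_len(nrow(em)), U = attr(p, "U"), p = as.numeric(p))
}

# emission block for one mark, columns named by individual
emission_block <- function(model, mark = NULL) {
  stopifnot(inherits(model, "gp_hmm"))
  marks <- unique(model$tracks$mark)
  if (is.null(mark)) {
    if (length(marks) > 1) stop("multi-mark model: specify the mark")
    mark <- marks
  }
  cols <- which(model$tracks$mark == mark)
  if (length(cols) == 0) stop("unknown mark")
  em <- model$emission[, cols, drop = FALSE]
  colnames(em) <- model$tracks$individual[cols]
  em
}

align_labels <- function(labels, individuals) {
  if (!is.null(names(labels))) {
    labels <- labels[individuals]
    if (anyNA(labels)) stop("labels missing for some individuals")
  } else if (length(labels) != length(individuals)) {
    stop("labels must cover every individual")
  }
  as.integer(labels)
}

# Precompute what repeated MWU tests on the same emission values need:
# per-state ranks, and either tie-corrected normal moments or the exact
# U distribution (all choose(n, n_case) assignments).
mwu_prepare <- function(em, labels, max_exact = 2e6) {
  n <- ncol(em)
  n1 <- sum(labels == 1); n0 <- n - n1
  R <- t(apply(em, 1, rank))
  mu <- n1 * n0 / 2
  exact <- min(n1, n0) < 8
  if (exact && choose(n, n1) > max_exact) {
    warning("exact MWU enumeration too large; using normal approximation")
    exact <- FALSE
  }
  out <- list(R = R, n = n, n1 = n1, n0 = n0, mu = mu, exact = exact)
  if (exact) {
    combs <- utils::combn(n, n1)
    ind <- matrix(0, n, ncol(combs))
    ind[cbind(as.vector(combs),
              rep(seq_len(ncol(combs)), each = n1))] <- 1
    out$U_null <- (R %*% ind) - n1 * (n1 + 1) / 2  # k x n_assignments
  } else {
    ties <- apply(em, 1, function(x) {
      tt <- table(x)
      sum(tt^3 - tt)
    })
    out$sigma <- sqrt(n1 * n0 / 12 * ((n + 1) - ties / (n * (n - 1))))
  }
  out
}

# p-values for one labeling; g = 0/1 case indicator vector (or a matrix with
# one labeling per column). Returns a k x n_labelings matrix.
mwu_pvalues <- function(mw, g) {
  g <- as.matrix(g)
  U <- (mw$R %*% g) - mw$n1 * (mw$n1 + 1) / 2
  if (mw$exact) {
    p <- U
    for (s in seq_len(nrow(U))) {
      dists <- abs(mw$U_null[s, ] - mw$mu)
      p[s, ] <- vapply(abs(U[s, ] - mw$mu) - 1e-9, function(d)
        mean(dists >= d), numeric(1))
    }
  } else {
    z <- (U - mw$mu) / mw$sigma
    p <- pmin(2 * stats::pnorm(-abs(z)), 1)
    p[mw$sigma == 0, ] <- 1  # all-tied state: no evidence either way
  }
  attr(p, "U") <- U
  p
}

#' Min-p permutation adjustment for phenotype association
#'
#' Family-wise error control across states: labels are shuffled `n_perm`
#' times; each shuffle records the minimum per-state Mann-Whitney p-value.
#' The adjusted p of a state is the fraction of null minima strictly smaller
#' ("more significant") than its observed p. Because that fraction can be
#' exactly zero, the add-one smoothed estimate `(1 + count) / (1 + n_perm)`
#' is reported alongside.
#'
#' @inheritParams mwu_phenotype
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed.
#' @return data.frame with state, U, p, p_adj, p_adj_smoothed, significant
#'   (p_adj < 0.05); the null minima as attribute `"null_min"`.
#' @export
permutation_adjust <- function(model, mark = NULL, labels, n_perm = 1000L,
                               seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  em <- emission_block(model, mark)
  labels <- align_labels(labels, colnames(em))
  mw <- mwu_prepare(em, labels)
  obs <- mwu_pvalues(mw, as.numeric(labels == 1))
  set.seed(seed)
  gmat <- vapply(seq_len(n_perm), function(i) sample(labels) == 1,
                 numeric(mw$n))
  null_p <- mwu_pvalues(mw, gmat)
  null_min <- apply(null_p, 2, min)
  p_adj <- vapply(obs[, 1], function(p) mean(null_min < p), numeric(1))
  out <- data.frame(state = seq_len(nrow(em)), U = attr(obs, "U")[, 1],
                    p = obs[, 1], p_adj = p_adj,
                    p_adj_smoothed = (1 + vapply(obs[, 1], function(p)
                      sum(null_min < p), numeric(1))) / (1 + n_perm))
  out$significant <- out$p_adj < 0.05
  attr(out, "null_min") <- null_min
  out
}

#' Covariate-adjusted logistic check of a phenotype association
#'
#' Maximum-likelihood logistic regression of the case/control label on one
#' state's per-individual emission parameters plus covariates, with a Wald
#' z-test on the emission coefficient. Complements the rank test by
#' directly adjusting for known covariates.
#'
#' @param state_emissions numeric vector of per-individual emissions.
#' @param labels 0/1 vector, same order.
#' @param covariates optional data.frame/matrix of per-individual covariates.
#' @return list with `coefficient`, `z`, `p`, `converged`. Perfect
#'   separation is reported as `converged = FALSE` with `p = NA`.
#' @export
logistic_covariate_check <- function(state_emissions, labels,
                                     covariates = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  X <- cbind(1, emission = state_emissions,
             if (!is.null(covariates)) as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  df <- data.frame(y = labels, emission = state_emissions)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sep <- warned || !fit$converged ||
    max(abs(stats::coef(fit)["emission"])) > 1e3
  if (sep)
    return(list(coefficient = unname(stats::coef(fit)["emission"]),
                z = NA_real_, p = NA_real_, converged = FALSE))
  sm <- summary(fit)$coefficients
  list(coefficient = sm["emission", 1], z = sm["emission", 3],
       p = sm["emission", 4], converged = TRUE)
}
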