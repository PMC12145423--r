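#' Global-pattern QTL discovery
#'
#' Emission-as-phenotype genetic association. The emission matrix is split
#' by mark; for every (state, mark), the per-individual emission parameters
#' form a quantitative phenotype that is regressed on each SNP's dosage
#' (with intercept and optional covariates, e.g. genotype PCs), and the
#' dosage coefficient is tested two-sided. Significance uses a Bonferroni
#' threshold of `alpha / (m * k)` where `m` is the number of marks and `k`
#' the number of states — the genome-wide level divided by the number of
#' emission phenotypes.
#'
#' @param model a fitted `gp_hmm`.
#' @param genotypes a [genotype_matrix()]; column names must contain the
#'   model's individual ids.
#' @param covariate_pcs optional individuals x covariates matrix (rows in
#'   genotype column order), e.g. from [genotype_pcs()].
#' @param maf_min minor-allele-frequency filter (default 0.05).
#' @param alpha genome-wide significance level before the m*k correction
#'   (default 5e-8).
#' @return data.frame of class `gqtl_result` with one row per
#'   (SNP, state, mark): snp, chrom, pos, state, mark, maf, beta, t, p,
#'   p_adj (Bonferroni, `min(1, p*m*k)`), significant. The threshold and
#'   family size are attached as attributes `threshold` and `family`.
#' @export
associate_gqtl <- function(model, genotypes, covariate_pcs = NULL,
                           maf_min = 0.05, alpha = 5e-8) {
  stopifnot(inherits(model, "gp_hmm"), inherits(genotypes, "genotype_matrix"))
  inds <- unique(model$tracks$individual)
  gcol <- match(inds, colnames(genotypes$dosages))
  if (anyNA(gcol)) stop("genotypes missing individuals present in the model")
  keep <- which(genotypes$maf >= maf_min)
  if (length(keep) == 0) stop("no SNPs pass the MAF filter")
  X <- t(genotypes$dosages[keep, gcol, drop = FALSE])
  const <- apply(X, 2, function(x) length(unique(x)) == 1)
  if (any(const)) {
    warning(sprintf("%d SNPs constant across model individuals: skipped",
                    sum(const)))
    keep <- keep[!const]
    X <- X[, !const, drop = FALSE]
  }
  covs <- if (!is.null(covariate_pcs))
    as.matrix(covariate_pcs)[gcol, , drop = FALSE] else NULL
  if (nrow(X) <= (if (is.null(covs)) 0 else ncol(covs)) + 2)
    stop("too few individuals for the association design")

  marks <- unique(model$tracks$mark)
  m <- length(marks); k <- model$k
  family <- m * k
  thr <- alpha / family
  out <- vector("list", m)
  for (j in seq_along(marks)) {
    cols <- which(model$tracks$mark == marks[j])
    cols <- cols[match(inds, model$tracks$individual[cols])]
    Y <- t(model$emission[, cols, drop = FALSE])  # individuals x states
    fit <- fast_lm_assoc(Y, X, covs)
    out[[j]] <- data.frame(
      snp = rep(genotypes$snps$id[keep], times = k),
      chrom = rep(genotypes$snps$chrom[keep], times = k),
      pos = rep(genotypes$snps$pos[keep], times = k),
      state = rep(seq_len(k), each = length(keep)),
      mark = marks[j],
      maf = rep(genotypes$maf[keep], times = k),
      beta = as.numeric(fit$beta),
      t = as.numeric(fit$t),
      p = as.numeric(fit$p),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adj <- pmin(1, res$p * family)
  res$significant <- res$p < thr
  attr(res, "threshold") <- thr
  attr(res, "family") <- family
  class(res) <- c("gqtl_result", "data.frame")
  res
}

#' Choose the number of states by gQTL count
#'
#' Runs [associate_gqtl()] for each candidate model and returns the one with
#' the most significant (SNP, state, mark) triples; ties go to the smaller
#' k. A typical grid evaluates models with 5-100 states in increments of
#' five.
#'
#' @param models list of `gp_hmm` objects (different k).
#' @param genotypes a [genotype_matrix()].
#' @param covariate_pcs optional covariates as in [associate_gqtl()].
#' @param ... passed to [associate_gqtl()].
#' @return list with `model` (the chosen fit), `k`, and `counts`
#'   (data.frame k / n_gqtl / n_snps per candidate).
#' @export
select_model <- function(models, genotypes, covariate_pcs = NULL, ...) {
  stopifnot(length(models) >= 1)
  counts <- data.frame(k = vapply(models, function(m) m$k, integer(1)),
                       n_gqtl = NA_integer_, n_snps = NA_integer_)
  for (i in seq_along(models)) {
    res <- associate_gqtl(models[[i]], genotypes, covariate_pcs, ...)
    sig <- res[res$significant, , drop = FALSE]
    counts$n_gqtl[i] <- nrow(sig)
    counts$n_snps[i] <- length(unique(sig$snp))
  }
  ord <- order(-counts$n_gqtl, counts$k)
  best <- ord[1]
  list(model = models[[best]], k = counts$k[best], counts = counts)
}

#' Replication scoring of discovered gQTLs
#'
#' Re-associates discovery gQTL SNPs in an independent data set, keeping for
#' each SNP its minimum p across the replication model's nonsingleton states
#' (see [classify_singletons()]), and asks whether the collection of
#' replication p-values is smaller than uniform via a two-sided
#' Mann-Whitney U test against a large seeded Uniform(0,1) reference sample.
#'
#' @param discovery_hits character vector of SNP ids, or a `gqtl_result`
#'   (its significant rows' SNPs are used).
#' @param replication_model `gp_hmm` fit on the replication data.
#' @param replication_genotypes [genotype_matrix()] for the replication
#'   individuals.
#' @param covariate_pcs optional covariates for the replication association.
#' @param nonsingleton_only restrict to nonsingleton states (default TRUE).
#' @param n_ref size of the uniform reference sample (default 1e5).
#' @param seed seed for the reference sample.
#' @return list with `p_values` (per-SNP minimum replication p), `mwu_p`
#'   (uniformity test p), `median_p`, `n_snps`, `states_used`.
#' @export
replicate_gqtls <- function(discovery_hits, replication_model,
                            replication_genotypes, covariate_pcs = NULL,
                            nonsingleton_only = TRUE, n_ref = 1e5,
                            seed = 1L) {
  snps <- if (inherits(discovery_hits, "gqtl_result"))
    unique(discovery_hits$snp[discovery_hits$significant])
  else unique(as.character(discovery_hits))
  shared <- intersect(snps, replication_genotypes$snps$id)
  if (length(shared) == 0)
    stop("no discovery gQTL SNPs are present in the replication genotypes")

  marks <- unique(replication_model$tracks$mark)
  states_used <- seq_len(replication_model$k)
  if (nonsingleton_only) {
    lab <- lapply(marks, function(m)
      classify_singletons(replication_model, mark = m))
    nonsing <- Reduce(`|`, lapply(lab, function(x) x == "nonsingleton"))
    states_used <- which(nonsing)
    if (length(states_used) == 0) stop("no nonsingleton states to test")
  }
  sub_idx <- match(shared, replication_genotypes$snps$id)
  sub <- genotype_matrix(
    replication_genotypes$dosages[sub_idx, , drop = FALSE],
    replication_genotypes$snps[sub_idx, , drop = FALSE])
  res <- associate_gqtl(replication_model, sub, covariate_pcs, maf_min = 0)
  res <- res[res$state %in% states_used, , drop = FALSE]
  pmin_snp <- tapply(res$p, res$snp, min, na.rm = TRUE)
  set.seed(seed)
  ref <- stats::runif(n_ref)
  mwu <- stats::wilcox.test(as.numeric(pmin_snp), ref)
  list(p_values = pmin_snp, mwu_p = mwu$p.value,
       median_p = stats::median(pmin_snp), n_snps = length(pmin_snp),
       states_used = states_used)
}

#' gQTL / eQTL overlap via MAF-matched SNP permutations
#'
#' Counts how many genes get a Bonferroni-significant eQTL when testing the
#' gQTL SNP set against all genes (per gene, only the top-most significant
#' SNP is considered; family = all (SNP, gene) tests performed), then
#' repeats the count for `n_perm` random SNP sets of the same size and MAF
#' distribution (matched within 5-percentage-point MAF bins) and reports
#' the fraction of permutations with fewer significant eQTLs than observed.
#'
#' @param gqtl_snps character vector of SNP ids (the observed set).
#' @param genotypes [genotype_matrix()] covering the expression individuals.
#' @param expression genes x individuals matrix; column names are individual
#'   ids present in the genotypes.
#' @param n_perm number of random SNP sets (default 100; 0 = observed only).
#' @param seed RNG seed for the permutations.
#' @param alpha Bonferroni level for eQTL significance (default 0.05).
#' @param maf_bin width of the MAF matching bins (default 0.05).
#' @return list with `observed` (significant eQTL count), `perm_counts`,
#'   `percentile` (fraction of permutations strictly below observed; NULL
#'   when `n_perm = 0`), and `n_tests`.
#' @export
eqtl_overlap_permutation <- function(gqtl_snps, genotypes, expression,
                                     n_perm = 100L, seed = 1L, alpha = 0.05,
                                     maf_bin = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  expression <- as.matrix(expression)
  gcol <- match(colnames(expression), colnames(genotypes$dosages))
  if (anyNA(gcol)) stop("expression individuals must be a subset of genotype individuals")
  idx_obs <- match(unique(gqtl_snps), genotypes$snps$id)
  if (anyNA(idx_obs)) stop("unknown SNP ids in gqtl_snps")

  Y <- t(expression)  # individuals x genes
  count_sig <- function(snp_idx) {
    X <- t(genotypes$dosages[snp_idx, gcol, drop = FALSE])
    ok <- apply(X, 2, function(x) length(unique(x)) > 1)
    if (!any(ok)) return(c(count = 0L, tests = 0L))
    p <- fast_lm_assoc(Y, X[, ok, drop = FALSE])$p
    n_tests <- sum(ok) * ncol(Y)
    top <- apply(p, 2, min, na.rm = TRUE)  # per-gene top SNP
    c(count = sum(top < alpha / n_tests), tests = n_tests)
  }
  obs <- count_sig(idx_obs)
  if (n_perm == 0)
    return(list(observed = unname(obs["count"]), perm_counts = integer(0),
                percentile = NULL, n_tests = unname(obs["tests"])))

  sets <- maf_matched_sets(genotypes$maf, idx_obs, n_perm, maf_bin, seed)
  perm_counts <- vapply(sets, function(pick)
    count_sig(unique(pick))[["count"]], numeric(1))
  list(observed = unname(obs["count"]), perm_counts = perm_counts,
       percentile = mean(perm_counts < obs["count"]),
       n_tests = unname(obs["tests"]))
}

# random SNP index sets matching the observed set's MAF-bin composition
maf_matched_sets <- function(maf, idx_obs, n_perm, maf_bin = 0.05,
                             seed = 1L) {
  breaks <- seq(0, 0.5 + maf_bin, by = maf_bin)
  all_bins <- cut(maf, breaks, include.lowest = TRUE)
  obs_bins <- table(all_bins[idx_obs])
  set.seed(seed)
  lapply(seq_len(n_perm), function(r) {
    pick <- integer(0)
    for (b in names(obs_bins)[obs_bins > 0]) {
      pool <- which(all_bins == b)
      need <- obs_bins[[b]]
      if (length(pool) >= need) {
        pick <- c(pick, sample(pool, need))
      } else {
        warning(sprintf("MAF bin %s has %d SNPs for %d needed: sampling with replacement",
                        b, length(pool), need))
        pick <- c(pick, sample(pool, need, replace = TRUE))
      }
    }
    pick
  })
}
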