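#' Synthetic study configuration
#'
#' Describes a synthetic multi-individual epigenome with the statistical
#' structure the downstream analysis assumes: a first-order Markov state path
#' over 200 bp bins, per-state per-track Bernoulli presence probabilities
#' ("true emissions"), a two-rate Poisson count gate, per-track multiplicative
#' covariate effects, genotypes whose dosage linearly shifts per-individual
#' presence probability in chosen states, expression/protein values linearly
#' coupled to emission parameters, and case/control labels shifting chosen
#' states' emissions.
#'
#' @param n_individuals number of individuals.
#' @param marks character vector of mark names (e.g. `c("H3K27ac")`).
#' @param n_bins total number of 200 bp bins, split across chromosomes.
#' @param n_chroms number of chromosomes (independent chains).
#' @param n_states_true number of true hidden states (`k_true`).
#' @param self_transition probability of staying in the current state.
#' @param emission_arch either a `k_true x D` matrix of presence
#'   probabilities (D = individuals x marks, mark-major track order) or a
#'   list understood by [emission_architecture()] (fields `p_on`, `p_off`,
#'   `active_sets`, `mark_concordant`).
#' @param count_rates length-2 numeric `(lambda_low, lambda_high)`: Poisson
#'   rates for absent/present signal. Must satisfy
#'   `lambda_high > lambda_low > 0`.
#' @param covariates `NULL`, or a list with `effects` (numeric vector, one
#'   log-scale coefficient per covariate) and optionally `values` (data.frame
#'   with one row per track); values are drawn standard normal when omitted.
#' @param gqtl_plan list of `list(snp, state, shift)`: SNP `snp`'s dosage
#'   shifts presence probability in `state` by `shift` per dose (clamped).
#' @param expr_plan list of `list(gene, state, mark, slope, noise_sd)` links
#'   from emission parameters to gene expression.
#' @param pheno_plan `NULL` or `list(states, case_shift)`: case individuals'
#'   presence probability in `states` is shifted by `case_shift`.
#' @param n_snps,maf_range genotype panel size and minor-allele-frequency
#'   range (drawn uniformly; range within (0, 0.5]).
#' @param n_genes number of genes for the expression matrix.
#' @param seed integer global seed; each `simulate_*` stage derives its own
#'   stream from it so stages are individually reproducible.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 20,
                         marks = "H3K27ac",
                         n_bins = 20000,
                         n_chroms = 2,
                         n_states_true = 5,
                         self_transition = 0.9,
                         emission_arch = list(p_on = 0.9, p_off = 0.05),
                         count_rates = c(1, 20),
                         covariates = NULL,
                         gqtl_plan = list(),
                         expr_plan = list(),
                         pheno_plan = NULL,
                         n_snps = 100,
                         maf_range = c(0.1, 0.5),
                         n_genes = 200,
                         seed = 1L) {
  stopifnot(n_individuals >= 1, n_bins >= n_chroms, n_chroms >= 1,
            n_states_true >= 1, length(marks) >= 1)
  if (self_transition < 0 || self_transition > 1)
    stop("self_transition must be a probability")
  if (!(count_rates[2] > count_rates[1] && count_rates[1] > 0))
    stop("count_rates must satisfy lambda_high > lambda_low > 0")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be within (0, 0.5]")
  d <- n_individuals * length(marks)
  if (is.matrix(emission_arch)) {
    if (nrow(emission_arch) != n_states_true || ncol(emission_arch) != d)
      stop("emission_arch matrix must be k_true x (individuals*marks)")
    if (any(emission_arch < 0 | emission_arch > 1))
      stop("emission probabilities must be in [0, 1]")
  }
  for (g in gqtl_plan)
    if (g$state < 1 || g$state > n_states_true)
      stop("gqtl_plan references a state outside 1..k_true")
  for (e in expr_plan) {
    if (e$state < 1 || e$state > n_states_true)
      stop("expr_plan references a state outside 1..k_true")
    if (!e$mark %in% marks) stop("expr_plan references an unknown mark")
    if (!is.finite(e$slope)) stop("expr_plan slopes must be finite")
  }
  if (!is.null(pheno_plan) &&
      (any(pheno_plan$states < 1) || any(pheno_plan$states > n_states_true)))
    stop("pheno_plan references a state outside 1..k_true")
  structure(list(n_individuals = as.integer(n_individuals), marks = marks,
                 n_bins = as.integer(n_bins), n_chroms = as.integer(n_chroms),
                 n_states_true = as.integer(n_states_true),
                 self_transition = self_transition,
                 emission_arch = emission_arch, count_rates = count_rates,
                 covariates = covariates, gqtl_plan = gqtl_plan,
                 expr_plan = expr_plan, pheno_plan = pheno_plan,
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_genes = as.integer(n_genes), seed = as.integer(seed)),
            class = "synth_config")
}

# Stage-specific seed stream derived from the global seed; keeps every
# simulate_* operation individually reproducible. Kept below 2^31.
stage_seed <- function(seed, stage) {
  offs <- c(truth = 101L, counts = 211L, genotypes = 307L,
            expression = 401L, intervals = 503L, labels = 601L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483647L
}

#' Build a block-structured true emission matrix
#'
#' Each state is "active" in a subset of individuals: active tracks emit a
#' presence call with probability `p_on`, all others with `p_off`. With
#' `mark_concordant = TRUE` (the default) the same individual subset is
#' active in every mark, emulating the co-occurrence of promoter/enhancer
#' marks across individuals.
#'
#' @param k number of states.
#' @param n_individuals number of individuals.
#' @param marks mark names.
#' @param active_sets optional list (length `k`) of individual index vectors;
#'   drawn at random (each individual active with probability 1/2) when
#'   omitted. Empty sets give all-background states.
#' @param p_on,p_off presence probability for active/background tracks.
#' @param mark_concordant if FALSE each mark gets an independent active set.
#' @param seed RNG seed for random active sets.
#' @return `k x (n_individuals * length(marks))` matrix, mark-major columns.
#' @export
emission_architecture <- function(k, n_individuals, marks,
                                  active_sets = NULL, p_on = 0.9,
                                  p_off = 0.05, mark_concordant = TRUE,
                                  seed = 1L) {
  stopifnot(p_on >= 0, p_on <= 1, p_off >= 0, p_off <= 1)
  m <- length(marks)
  if (is.null(active_sets)) {
    set.seed(seed)
    active_sets <- lapply(seq_len(k), function(i)
      which(stats::runif(n_individuals) < 0.5))
  }
  stopifnot(length(active_sets) == k)
  em <- matrix(p_off, nrow = k, ncol = n_individuals * m)
  for (s in seq_len(k)) {
    if (mark_concordant) {
      for (j in seq_len(m))
        em[s, (j - 1) * n_individuals + active_sets[[s]]] <- p_on
    } else {
      set.seed(seed + 31L * s)
      for (j in seq_len(m)) {
        act <- which(stats::runif(n_individuals) < 0.5)
        em[s, (j - 1) * n_individuals + act] <- p_on
      }
    }
  }
  em
}

# Track table in mark-major order: for each mark, all individuals in the
# same order (the convention every downstream module assumes).
track_table <- function(config) {
  data.frame(
    individual = rep(sprintf("ind%03d", seq_len(config$n_individuals)),
                     times = length(config$marks)),
    mark = rep(config$marks, each = config$n_individuals),
    stringsAsFactors = FALSE
  )
}

bin_table <- function(config) {
  per <- diff(floor(seq(0, config$n_bins, length.out = config$n_chroms + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chroms)), per)
  start <- unlist(lapply(per, function(n) 200 * (seq_len(n) - 1)))
  data.frame(chrom = chrom, start = start, end = start + 200,
             stringsAsFactors = FALSE)
}

#' Simulate the hidden ground truth
#'
#' Realizes the latent layer of the generative model: a first-order Markov
#' state path over bins (chromosomes are independent chains with uniform
#' initial state; transition keeps the current state with probability
#' `self_transition`, otherwise moves uniformly to another state) and the
#' true emission matrix, plus records of every planted effect so downstream
#' recovery can be scored.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_truth` with `state_path` (per-bin state),
#'   `bins`, `tracks`, `true_emissions` (`k_true x D`), `planted_gqtls`,
#'   `planted_expression_links`, `planted_phenotype_states`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  k <- config$n_states_true
  arch <- config$emission_arch
  if (is.matrix(arch)) {
    em <- arch
  } else {
    em <- emission_architecture(
      k, config$n_individuals, config$marks,
      active_sets = arch$active_sets,
      p_on = if (is.null(arch$p_on)) 0.9 else arch$p_on,
      p_off = if (is.null(arch$p_off)) 0.05 else arch$p_off,
      mark_concordant = if (is.null(arch$mark_concordant)) TRUE
                        else arch$mark_concordant,
      seed = config$seed)
  }
  bins <- bin_table(config)
  set.seed(stage_seed(config$seed, "truth"))
  state <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    state[idx] <- markov_path(length(idx), k, config$self_transition)
  }
  structure(list(state_path = state, bins = bins, tracks = track_table(config),
                 true_emissions = em,
                 planted_gqtls = config$gqtl_plan,
                 planted_expression_links = config$expr_plan,
                 planted_phenotype_states = config$pheno_plan),
            class = "synth_truth")
}

# One chain: uniform start; stay with prob s, else uniform over other states.
markov_path <- function(n, k, s) {
  if (k == 1) return(rep(1L, n))
  path <- integer(n)
  path[1] <- sample.int(k, 1)
  stay <- stats::runif(n - 1) < s
  jump_to <- sample.int(k - 1, n - 1, replace = TRUE)
  for (t in seq_len(n - 1)) {
    if (stay[t]) {
      path[t + 1] <- path[t]
    } else {
      j <- jump_to[t]
      path[t + 1] <- if (j >= path[t]) j + 1L else j
    }
  }
  path
}

#' Simulate binned read counts from the ground truth
#'
#' For bin `b` and track `d`, presence `z ~ Bernoulli(p)` where `p` is the
#' true emission probability of the bin's state, shifted by any planted
#' genotype dose-response or case/control effect for that individual
#' (clamped to \[0, 1\]); the read count is then Poisson with rate
#' `lambda_high` (present) or `lambda_low` (absent) times the multiplicative
#' covariate factor `exp(sum_j beta_j x_dj)`.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [synth_config()].
#' @param genotypes a `genotype_matrix` (required when `gqtl_plan` is
#'   non-empty).
#' @param labels optional 0/1 case labels per individual (required when
#'   `pheno_plan` is set).
#' @return list with `counts` (a [binned_track_matrix()]), `covariates`
#'   (data.frame, one row per track; zero columns when none configured) and
#'   `presence` (the latent 0/1 matrix, for calibration tests).
#' @export
simulate_counts <- function(truth, config, genotypes = NULL, labels = NULL) {
  stopifnot(inherits(truth, "synth_truth"), inherits(config, "synth_config"))
  if (length(config$gqtl_plan) > 0 && is.null(genotypes))
    stop("gqtl_plan is set: pass the genotypes whose dosages drive it")
  if (!is.null(config$pheno_plan) && is.null(labels))
    stop("pheno_plan is set: pass per-individual case labels")
  n_ind <- config$n_individuals
  tr <- truth$tracks
  ind_idx <- match(tr$individual, sprintf("ind%03d", seq_len(n_ind)))
  set.seed(stage_seed(config$seed, "counts"))

  p <- truth$true_emissions[truth$state_path, , drop = FALSE]
  for (g in config$gqtl_plan) {
    dose <- genotypes$dosages[g$snp, ]
    rows <- truth$state_path == g$state
    p[rows, ] <- p[rows, , drop = FALSE] +
      rep(dose[ind_idx] * g$shift, each = sum(rows))
  }
  if (!is.null(config$pheno_plan)) {
    shift_ind <- labels[ind_idx] * config$pheno_plan$case_shift
    rows <- truth$state_path %in% config$pheno_plan$states
    p[rows, ] <- p[rows, , drop = FALSE] + rep(shift_ind, each = sum(rows))
  }
  p <- pmin(pmax(p, 0), 1)

  z <- matrix(stats::runif(length(p)) < p, nrow = nrow(p))
  lam <- ifelse(z, config$count_rates[2], config$count_rates[1])

  cov_tab <- data.frame(row.names = seq_len(ncol(p)))
  if (!is.null(config$covariates)) {
    eff <- config$covariates$effects
    vals <- config$covariates$values
    if (is.null(vals)) {
      vals <- as.data.frame(matrix(stats::rnorm(ncol(p) * length(eff)),
                                   ncol = length(eff)))
      names(vals) <- paste0("cov", seq_along(eff))
    }
    stopifnot(nrow(vals) == ncol(p), ncol(vals) == length(eff))
    fac <- exp(as.matrix(vals) %*% eff)
    lam <- sweep(lam, 2, as.numeric(fac), `*`)
    cov_tab <- vals
  }
  counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
  list(counts = binned_track_matrix(counts, truth$bins, tr),
       covariates = cov_tab,
       presence = z * 1L)
}

#' Simulate a genotype panel under Hardy-Weinberg equilibrium
#'
#' Allele frequencies are drawn uniformly from `maf_range`; dosages are
#' Binomial(2, freq) per individual, independently across SNPs (no linkage
#' disequilibrium). SNP positions are placed uniformly on the synthetic
#' chromosomes.
#'
#' @param config a [synth_config()].
#' @return a `genotype_matrix` (see [genotype_matrix()]).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  n_snps <- config$n_snps
  n_ind <- config$n_individuals
  af <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
  dos <- matrix(stats::rbinom(n_snps * n_ind, 2, rep(af, n_ind)),
                nrow = n_snps)
  bins <- bin_table(config)
  pick <- sample.int(nrow(bins), n_snps, replace = TRUE)
  snps <- data.frame(chrom = bins$chrom[pick],
                     pos = bins$start[pick] + sample.int(200, n_snps, TRUE),
                     id = sprintf("snp%05d", seq_len(n_snps)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  colnames(dos) <- sprintf("ind%03d", seq_len(n_ind))
  genotype_matrix(dos, snps)
}

#' Simulate gene expression coupled to emission parameters
#'
#' Planted genes follow `y = slope * e + noise`, where `e` is the
#' per-individual emission vector of the planted (state, mark); all other
#' genes are pure noise. Planted genes' TSS are placed inside a bin of
#' their target state so TSS-proximal coupling is geometrically realizable;
#' other TSS are uniform.
#'
#' @param truth a [simulate_truth()] result.
#' @param emissions `k x D` emission matrix to couple against — the truth's
#'   matrix or a fitted model's.
#' @param config the matching [synth_config()].
#' @return list with `expression` (genes x individuals matrix) and `tss`
#'   (data.frame gene/chrom/pos/strand).
#' @export
simulate_expression <- function(truth, emissions, config) {
  stopifnot(inherits(truth, "synth_truth"), inherits(config, "synth_config"))
  set.seed(stage_seed(config$seed, "expression"))
  n_ind <- config$n_individuals
  n_genes <- config$n_genes
  expr <- matrix(stats::rnorm(n_genes * n_ind), nrow = n_genes,
                 dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                 sprintf("ind%03d", seq_len(n_ind))))
  bins <- truth$bins
  pick <- sample.int(nrow(bins), n_genes, replace = TRUE)
  tss <- data.frame(gene = rownames(expr), chrom = bins$chrom[pick],
                    pos = bins$start[pick] + 100L,
                    strand = sample(c("+", "-"), n_genes, TRUE),
                    stringsAsFactors = FALSE)
  for (e in config$expr_plan) {
    mark_cols <- which(truth$tracks$mark == e$mark)
    evec <- emissions[e$state, mark_cols]
    expr[e$gene, ] <- e$slope * evec +
      stats::rnorm(n_ind, sd = e$noise_sd)
    in_state <- which(truth$state_path == e$state)
    if (length(in_state) == 0) stop("planted state has no bins")
    b <- in_state[sample.int(length(in_state), 1)]
    tss$chrom[e$gene] <- bins$chrom[b]
    tss$pos[e$gene] <- bins$start[b] + 100L
  }
  list(expression = expr, tss = tss)
}

#' Simulate interval annotations enriched in chosen states
#'
#' Draws single-bin intervals with sampling weights chosen so the expected
#' base-level fold enrichment of the target states equals `coverage_fold`
#' (weight `w = f(1-q)/(1-f q)` for target fold `f` at target genome
#' fraction `q`; uniform placement when `coverage_fold = 1`).
#'
#' @param truth a [simulate_truth()] result.
#' @param state_ids states the intervals should prefer.
#' @param coverage_fold desired fold enrichment (must satisfy
#'   `coverage_fold * target_fraction < 1`).
#' @param n_intervals number of intervals to draw.
#' @param label label for the resulting intervals.
#' @param seed RNG seed.
#' @return an [interval_set()].
#' @export
simulate_intervals <- function(truth, state_ids, coverage_fold,
                               n_intervals = 500, label = "planted",
                               seed = 1L) {
  stopifnot(inherits(truth, "synth_truth"), coverage_fold >= 0)
  set.seed(stage_seed(seed, "intervals"))
  target <- truth$state_path %in% state_ids
  q <- mean(target)
  if (coverage_fold * q >= 1)
    stop(sprintf("fold %.2f unattainable: target states cover fraction %.3f",
                 coverage_fold, q))
  w <- if (coverage_fold == 1) 1 else coverage_fold * (1 - q) / (1 - coverage_fold * q)
  prob <- ifelse(target, w, 1)
  pick <- sample.int(nrow(truth$bins), min(n_intervals, nrow(truth$bins)),
                     replace = FALSE, prob = prob)
  interval_set(data.frame(chrom = truth$bins$chrom[pick],
                          start = truth$bins$start[pick],
                          end = truth$bins$end[pick],
                          label = label))
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("synth_truth: %d bins, k_true=%d, %d tracks, %d planted gQTL(s), %d expression link(s)\n",
              length(x$state_path), nrow(x$true_emissions), nrow(x$tracks),
              length(x$planted_gqtls), length(x$planted_expression_links)))
  invisible(x)
}
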