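# helper: model with given per-(state, individual) emissions for one mark
model_from_emissions <- function(em, mark = "H3K27ac") {
  make_model(em, marks = mark)
}

# helper: genotype panel from a dosage matrix
geno_from <- function(dos, individuals = sprintf("ind%03d", seq_len(ncol(dos)))) {
  colnames(dos) <- individuals
  genotype_matrix(dos, data.frame(chrom = "chr1",
                                  pos = seq_len(nrow(dos)) * 1000,
                                  id = sprintf("snp%05d", seq_len(nrow(dos)))))
}

test_that("the Bonferroni family is the number of marks times states", {
  set.seed(1)
  n <- 12
  em <- matrix(runif(85 * 3 * n), nrow = 85)
  tracks <- data.frame(individual = rep(sprintf("ind%03d", 1:n), 3),
                       mark = rep(c("m1", "m2", "m3"), each = n))
  model <- make_model(em, marks = "x")
  model$tracks <- tracks
  model$tracks$track_id <- paste(tracks$individual, tracks$mark, sep = "_")
  colnames(model$emission) <- model$tracks$track_id
  g <- geno_from(matrix(rbinom(5 * n, 2, 0.4), 5))
  res <- associate_gqtl(model, g)
  expect_equal(attr(res, "family"), 3 * 85)
  expect_equal(attr(res, "threshold"), 5e-8 / (3 * 85))
  expect_true(all(res$p_adj >= res$p))
})

test_that("the dosage coefficient equals the closed-form covariance ratio", {
  # 5 individuals, hand-checkable OLS
  dos <- matrix(c(0L, 1L, 2L, 1L, 0L), 1)
  y <- c(0.2, 0.5, 0.9, 0.45, 0.15)
  em <- matrix(y, 1)
  model <- model_from_emissions(em)
  res <- associate_gqtl(model, geno_from(dos), maf_min = 0)
  beta_hand <- cov(y, dos[1, ]) / var(dos[1, ])
  expect_equal(res$beta, beta_hand, tolerance = 1e-12)
  ref <- summary(lm(y ~ dos[1, ]))$coefficients
  expect_equal(res$t, ref[2, 3], tolerance = 1e-10)
  expect_equal(res$p, ref[2, 4], tolerance = 1e-10)
})

test_that("association matches lm with covariates and is order-invariant", {
  set.seed(21)
  n <- 30
  em <- matrix(runif(3 * n), 3)
  dos <- matrix(rbinom(4 * n, 2, 0.3), 4)
  pcs <- matrix(rnorm(n * 2), n)
  model <- model_from_emissions(em)
  res <- associate_gqtl(model, geno_from(dos), covariate_pcs = pcs,
                        maf_min = 0)
  i <- res$snp == "snp00002" & res$state == 3
  ref <- summary(lm(em[3, ] ~ dos[2, ] + pcs))$coefficients
  expect_equal(res$beta[i], ref[2, 1], tolerance = 1e-10)
  expect_equal(res$p[i], ref[2, 4], tolerance = 1e-10)

  # reorder individuals consistently: identical p-values
  perm <- sample(n)
  model2 <- model_from_emissions(em[, perm, drop = FALSE])
  model2$tracks$individual <- model$tracks$individual[perm]
  model2$tracks$track_id <- paste(model2$tracks$individual,
                                  model2$tracks$mark, sep = "_")
  colnames(model2$emission) <- model2$tracks$track_id
  res2 <- associate_gqtl(model2, geno_from(dos), covariate_pcs = pcs,
                         maf_min = 0)
  expect_equal(res2$p[order(res2$snp, res2$state)],
               res$p[order(res$snp, res$state)], tolerance = 1e-10)
})

test_that("null gQTL tests are calibrated at the nominal level", {
  set.seed(7)
  n <- 50
  em <- matrix(runif(50 * n), 50)             # 50 null "phenotypes"
  dos <- matrix(rbinom(200 * n, 2, runif(200 * n, 0.1, 0.5)), 200)
  model <- model_from_emissions(em)
  res <- associate_gqtl(model, geno_from(dos), maf_min = 0)
  expect_equal(nrow(res), 200 * 50)
  rate <- mean(res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), 3 * se + 1e-3)
})

test_that("MAF filtering and constant dosages are handled", {
  set.seed(3)
  n <- 20
  dos <- rbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.02), rep(1L, n))
  em <- matrix(runif(2 * n), 2)
  model <- model_from_emissions(em)
  g <- geno_from(dos)
  expect_warning(res <- associate_gqtl(model, g, maf_min = 0), "constant")
  expect_warning(res2 <- associate_gqtl(model, g, maf_min = 0.05), "constant")
  expect_false("snp00002" %in% res2$snp)  # maf ~0.02 filtered
  expect_error(associate_gqtl(model, geno_from(dos[2, , drop = FALSE]),
                              maf_min = 0.4),
               "no SNPs")
})

test_that("model selection maximizes the significant-triple count", {
  set.seed(11)
  n <- 60
  dos <- matrix(rbinom(20 * n, 2, 0.4), 20)
  g <- geno_from(dos)
  # model B: two states' emissions driven by SNPs; model A: null
  emA <- matrix(runif(2 * n), 2)
  emB <- rbind(0.3 + 0.2 * dos[1, ] + rnorm(n, 0, 0.01),
               0.2 + 0.25 * dos[2, ] + rnorm(n, 0, 0.01),
               runif(n))
  mA <- model_from_emissions(emA); mA$k <- 2L
  mB <- model_from_emissions(pmin(pmax(emB, 0), 1)); mB$k <- 3L
  sel <- select_model(list(mA, mB), g)
  expect_equal(sel$k, 3)
  expect_equal(sel$counts$n_gqtl[1], 0)
  expect_gte(sel$counts$n_gqtl[2], 2)
  # single candidate returned trivially
  sel1 <- select_model(list(mA), g)
  expect_equal(sel1$k, 2)
  # ties break to the smaller k
  sel2 <- select_model(list(mA, model_from_emissions(matrix(runif(4 * n), 4))), g)
  expect_equal(sel2$k, 2)
})

test_that("replication of real signal rejects uniformity", {
  set.seed(17)
  n <- 50
  dos <- matrix(rbinom(30 * n, 2, 0.4), 30)
  g <- geno_from(dos)
  # discovery hits: SNPs 1-3 truly drive emissions in the replication model
  em <- rbind(0.3 + 0.2 * dos[1, ] + rnorm(n, 0, 0.02),
              0.3 + 0.2 * dos[2, ] + rnorm(n, 0, 0.02),
              0.3 + 0.2 * dos[3, ] + rnorm(n, 0, 0.02),
              matrix(runif(2 * n, 0.2, 0.6), 2))
  model <- model_from_emissions(pmin(pmax(em, 0), 1))
  rep1 <- replicate_gqtls(c("snp00001", "snp00002", "snp00003"), model, g,
                          seed = 5)
  expect_lt(rep1$mwu_p, 0.05)
  expect_lt(rep1$median_p, 0.5)
  expect_error(replicate_gqtls("snp99999", model, g), "no discovery")
})

test_that("singleton states are excluded from replication", {
  n <- 10
  em <- rbind(c(0.9, rep(0.1, n - 1)),     # singleton
              rep(0.3, n),
              runif(n, 0.3, 0.45))
  model <- model_from_emissions(em)
  set.seed(2)
  g <- geno_from(matrix(rbinom(5 * n, 2, 0.5), 5))
  r <- replicate_gqtls(c("snp00001", "snp00002"), model, g, seed = 1)
  expect_identical(r$states_used, 2:3)
  r_all <- replicate_gqtls(c("snp00001", "snp00002"), model, g,
                           nonsingleton_only = FALSE, seed = 1)
  expect_identical(r_all$states_used, 1:3)
})

test_that("MAF-matched permutation sets preserve bin composition", {
  set.seed(9)
  maf <- runif(500, 0.01, 0.5)
  idx_obs <- sample(500, 40)
  sets <- globpat:::maf_matched_sets(maf, idx_obs, n_perm = 20,
                                     maf_bin = 0.05, seed = 3)
  breaks <- seq(0, 0.55, by = 0.05)
  obs_tab <- table(cut(maf[idx_obs], breaks, include.lowest = TRUE))
  for (s in sets) {
    expect_length(s, 40)
    expect_equal(table(cut(maf[s], breaks, include.lowest = TRUE)), obs_tab)
  }
})

test_that("eQTL overlap percentile detects planted SNP-expression coupling", {
  set.seed(13)
  n <- 45; n_snps <- 120; n_genes <- 40
  dos <- matrix(rbinom(n_snps * n, 2, runif(n_snps * n, 0.1, 0.5)), n_snps)
  g <- geno_from(dos)
  expr <- matrix(rnorm(n_genes * n), n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 colnames(g$dosages)))
  gqtl_set <- sprintf("snp%05d", 1:10)
  for (i in 1:10)  # the gQTL SNPs also drive expression
    expr[i, ] <- 1.5 * dos[i, ] + rnorm(n, 0, 0.5)
  res <- eqtl_overlap_permutation(gqtl_set, g, expr, n_perm = 50, seed = 4)
  expect_gte(res$observed, 5)
  expect_gte(res$percentile, 0.9)
  # degenerate configuration: observed only
  res0 <- eqtl_overlap_permutation(gqtl_set, g, expr, n_perm = 0)
  expect_equal(res0$observed, res$observed)
  expect_null(res0$percentile)
})

test_that("genotype PCs reproduce prcomp scores", {
  set.seed(5)
  dos <- matrix(rbinom(200, 2, 0.4), 20)
  g <- geno_from(dos)
  pcs <- genotype_pcs(g, n_pcs = 3)
  ref <- prcomp(scale(t(dos)))$x[, 1:3]
  for (j in 1:3)
    expect_equal(abs(cor(pcs[, j], ref[, j])), 1, tolerance = 1e-8)
})
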