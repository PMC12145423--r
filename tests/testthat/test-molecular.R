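test_that("a perfect linear link gives machine-limited p with the right sign", {
  set.seed(1)
  n <- 20
  em <- matrix(runif(3 * n, 0.1, 0.9), 3)
  model <- make_model(em)
  meas <- rbind(gene_up = 2 + 3 * em[2, ], gene_dn = 1 - 2 * em[3, ])
  colnames(meas) <- model$tracks$individual
  res <- associate_emissions(model, "H3K27ac", meas)
  up <- res[res$feature == "gene_up" & res$state == 2, ]
  dn <- res[res$feature == "gene_dn" & res$state == 3, ]
  expect_lt(up$p, 1e-20)
  expect_gt(up$beta, 0)
  expect_lt(dn$p, 1e-20)
  expect_lt(dn$beta, 0)
})

test_that("p-values are invariant to affine rescaling of measurements", {
  set.seed(2)
  n <- 15
  em <- matrix(runif(2 * n, 0.2, 0.8), 2)
  model <- make_model(em)
  meas <- matrix(rnorm(4 * n), 4,
                 dimnames = list(paste0("f", 1:4), model$tracks$individual))
  r1 <- associate_emissions(model, "H3K27ac", meas)
  r2 <- associate_emissions(model, "H3K27ac", 100 + 7 * meas)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
})

test_that("null features rarely produce BH discoveries", {
  set.seed(3)
  n <- 30
  em <- matrix(runif(10 * n, 0.1, 0.9), 10)
  model <- make_model(em)
  any_disc <- vapply(1:40, function(i) {
    meas <- matrix(rnorm(25 * n), 25,
                   dimnames = list(paste0("f", 1:25),
                                   model$tracks$individual))
    any(associate_emissions(model, "H3K27ac", meas)$significant)
  }, logical(1))
  # BH controls FDR at 5%: on a global null, any discovery is an error
  expect_lte(mean(any_disc), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("planted expression links are recovered with high sensitivity", {
  plan <- lapply(1:10, function(i)
    list(gene = i, state = (i %% 4) + 1, mark = "H3K27ac", slope = 1,
         noise_sd = 0.1))
  cfg <- synth_config(n_individuals = 40, n_bins = 5000, n_states_true = 5,
                      n_genes = 100, expr_plan = plan, seed = 12)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression(tr, tr$true_emissions, cfg)
  model <- make_model(tr$true_emissions)
  res <- associate_emissions(model, "H3K27ac", ex$expression)
  hits <- vapply(plan, function(pl) {
    row <- res[res$feature == rownames(ex$expression)[pl$gene] &
                 res$state == pl$state, ]
    isTRUE(row$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("constant-emission states are skipped with a warning", {
  n <- 12
  em <- rbind(rep(0.5, n), runif(n))
  model <- make_model(em)
  meas <- matrix(rnorm(2 * n), 2,
                 dimnames = list(c("a", "b"), model$tracks$individual))
  expect_warning(res <- associate_emissions(model, "H3K27ac", meas),
                 "constant")
  expect_true(all(res$state == 2))
})

test_that("distance profile has the exact window geometry", {
  cfg <- synth_config(n_bins = 2e4, n_chroms = 1, n_states_true = 3,
                      n_genes = 10, seed = 5)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression(tr, tr$true_emissions, cfg)
  model <- make_model(tr$true_emissions)
  ann <- genome_annotation(tr$state_path, tr$bins, 3)
  prof <- distance_profile(ann, model, "H3K27ac", ex$expression, ex$tss)
  expect_equal(nrow(prof), 10000)
  expect_equal(min(prof$distance), -499950)
  expect_equal(max(prof$distance), 499950)
  expect_equal(diff(prof$distance)[1], 100)
  # genome is 4 Mb: genes near the ends contribute fewer windows
  expect_true(all(prof$n_genes <= 10))
})

test_that("profile at the TSS window equals the plain TSS-bin correlation", {
  set.seed(8)
  n <- 12
  em <- matrix(runif(3 * n, 0.1, 0.9), 3)
  model <- make_model(em)
  state <- rep(1:3, length.out = 5000)
  bins <- data.frame(chrom = "chr1", start = 200 * (0:4999),
                     end = 200 * (1:5000))
  ann <- genome_annotation(state, bins, 3)
  expr <- matrix(rnorm(n), 1, dimnames = list("g1", model$tracks$individual))
  tss <- data.frame(gene = "g1", chrom = "chr1", pos = 500100, strand = "+")
  prof <- distance_profile(ann, model, "H3K27ac", expr, tss)
  tss_bin_state <- state[500100 %/% 200 + 1]
  expected_r <- cor(expr[1, ], em[tss_bin_state, ])
  at_tss <- prof$mean_r[prof$distance == 50]
  expect_equal(at_tss, expected_r, tolerance = 1e-10)
})

test_that("TSS-proximal coupling decays with distance", {
  # one long chromosome; gene expression driven by the state at its TSS,
  # with high self-transition so the planted state persists locally
  arch <- emission_architecture(4, 30, "H3K27ac", p_on = 0.9, p_off = 0.05,
                                seed = 3)
  plan <- lapply(1:15, function(i)
    list(gene = i, state = 2, mark = "H3K27ac", slope = 1, noise_sd = 0.15))
  cfg <- synth_config(n_individuals = 30, n_bins = 5e4, n_chroms = 1,
                      n_states_true = 4, emission_arch = arch,
                      self_transition = 0.98, n_genes = 15,
                      expr_plan = plan, seed = 31)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression(tr, tr$true_emissions, cfg)
  model <- make_model(tr$true_emissions)
  ann <- genome_annotation(tr$state_path, tr$bins, 4)
  prof <- distance_profile(ann, model, "H3K27ac", ex$expression, ex$tss)
  near <- abs(prof$distance) < 2e4
  far <- abs(prof$distance) > 4e5
  expect_gt(mean(abs(prof$mean_r[near]), na.rm = TRUE),
            mean(abs(prof$mean_r[far]), na.rm = TRUE) + 0.1)
})

test_that("module eigengenes match direct eigendecomposition", {
  set.seed(7)
  n <- 50
  expr <- matrix(rnorm(50 * n), 50,
                 dimnames = list(paste0("g", 1:50), paste0("i", 1:n)))
  assign <- data.frame(gene = paste0("g", 1:50),
                       module = rep(c("blue", "brown"), each = 25))
  eig <- module_eigengenes(expr, assign)
  expect_equal(dim(eig), c(2, n))
  # variance explained equals the leading eigenvalue share of the gene
  # correlation matrix
  for (m in c("blue", "brown")) {
    genes <- assign$gene[assign$module == m]
    ev <- eigen(cor(t(expr[genes, ])), symmetric = TRUE)$values
    expect_equal(attr(eig, "var_explained")[[m]], ev[1] / sum(ev),
                 tolerance = 1e-10)
  }
  # eigengene is invariant (up to nothing -- sign fixed) to gene order
  eig2 <- module_eigengenes(expr[sample(50), ], assign)
  expect_equal(eig, eig2, tolerance = 1e-10)
})

test_that("degenerate modules behave as documented", {
  n <- 20
  g <- rnorm(n)
  expr <- rbind(a = g, b = g, c = rnorm(n))
  colnames(expr) <- paste0("i", 1:n)
  # duplicated gene: eigengene proportional to the standardized gene
  eig <- module_eigengenes(expr, data.frame(gene = c("a", "b"),
                                            module = "m1"))
  expect_equal(abs(cor(eig["m1", ], g)), 1, tolerance = 1e-10)
  expect_gt(cor(eig["m1", ], g), 0)  # sign convention
  expect_equal(attr(eig, "var_explained")[["m1"]], 1, tolerance = 1e-12)
  expect_error(module_eigengenes(expr, data.frame(gene = "a", module = "m")),
               "< 2 genes")
  expr2 <- rbind(a = rep(1, n), b = rep(2, n))
  colnames(expr2) <- paste0("i", 1:n)
  expect_error(module_eigengenes(expr2, data.frame(gene = c("a", "b"),
                                                   module = "m")),
               "constant")
})

test_that("gene/protein overlap combines Fisher test and shared states", {
  u <- paste0("g", 1:60)
  gene_res <- data.frame(feature = rep(paste0("g", 1:10), each = 2),
                         state = rep(1:2, 10), mark = "m",
                         significant = TRUE)
  prot_res <- data.frame(feature = rep(paste0("g", 6:15), each = 2),
                         state = rep(c(2L, 5L), 10), mark = "m",
                         significant = TRUE)
  res <- gene_protein_overlap(gene_res, prot_res, u)
  expect_equal(res$fisher$overlap, 5)
  # g6..g10 share state 2 on both platforms
  expect_equal(res$shared_state_count, 5)
  # identical sets: fold = |U| / |A|
  res2 <- gene_protein_overlap(paste0("g", 1:10), paste0("g", 1:10), u)
  expect_equal(res2$fisher$fold, 60 / 10)
  # disjoint: zero overlap
  res3 <- gene_protein_overlap(paste0("g", 1:5), paste0("g", 6:10), u)
  expect_equal(res3$fisher$overlap, 0)
})
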