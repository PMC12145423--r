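#' Associate emission parameters with molecular measurements
#'
#' For one mark, regresses each measured feature (gene expression, protein
#' abundance, module eigengene) on each state's per-individual emission
#' parameters over the shared individuals, with a two-sided t-test on the
#' slope and BH FDR within the mark. Emissions are model parameters, not
#' re-fit per individual subset: restricting to shared individuals only
#' subsets the emission vectors.
#'
#' @param model a fitted `gp_hmm`.
#' @param mark which mark's emission block to use.
#' @param measurements features x individuals numeric matrix; column names
#'   are individual ids (>= 3 must be shared with the model).
#' @return data.frame with feature, state, mark, beta, t, p, q (BH within
#'   mark), significant (q < 0.05). Constant-emission states are skipped
#'   with a warning.
#' @export
associate_emissions <- function(model, mark, measurements) {
  stopifnot(inherits(model, "gp_hmm"))
  measurements <- as.matrix(measurements)
  if (anyNA(measurements)) stop("measurements must not contain missing values")
  cols <- which(model$tracks$mark == mark)
  if (length(cols) == 0) stop("unknown mark")
  inds <- model$tracks$individual[cols]
  shared <- intersect(colnames(measurements), inds)
  if (length(shared) < 3) stop("need >= 3 shared individuals")
  X <- t(model$emission[, cols[match(shared, inds)], drop = FALSE])
  Y <- t(measurements[, shared, drop = FALSE])
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep))
    warning(sprintf("%d state(s) with constant emissions skipped", sum(!keep)))
  if (!any(keep)) stop("no state has varying emissions among shared individuals")
  fit <- fast_lm_assoc(Y, X[, keep, drop = FALSE])
  states <- seq_len(model$k)[keep]
  feats <- if (is.null(rownames(measurements)))
    as.character(seq_len(nrow(measurements))) else rownames(measurements)
  res <- data.frame(
    feature = rep(feats, each = length(states)),
    state = rep(states, times = length(feats)),
    mark = mark,
    beta = as.numeric(fit$beta), t = as.numeric(fit$t),
    p = as.numeric(fit$p), stringsAsFactors = FALSE)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < 0.05
  res
}

#' Distance-resolved expression-emission correlation profile
#'
#' For each gene, the +/- `span` region around its TSS is divided into
#' `2 * span / window` windows (10,000 for the 500 kb / 100 bp defaults).
#' Each window is assigned the global pattern of the 200 bp annotation bin
#' containing its midpoint, and the Pearson correlation between the gene's
#' expression and that pattern's per-individual emission parameters (for the
#' given mark) is recorded. The profile is the mean correlation per signed
#' TSS distance across genes; distances are signed relative to strand
#' (upstream negative). Windows beyond chromosome ends are skipped and the
#' per-distance denominators adjusted.
#'
#' @param annotation a [genome_annotation()].
#' @param model the `gp_hmm` that produced it.
#' @param mark which mark's emissions to correlate.
#' @param expression genes x individuals matrix (row names = gene ids).
#' @param tss_table data.frame with gene, chrom, pos, strand.
#' @param window window size in bases (default 100).
#' @param span half-width of the profiled region in bases (default 5e5).
#' @return data.frame with `distance` (signed window midpoint offset),
#'   `mean_r`, `n_genes`; the genes x states correlation matrix is attached
#'   as attribute `"gene_state_r"`.
#' @export
distance_profile <- function(annotation, model, mark, expression, tss_table,
                             window = 100, span = 500000) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(model, "gp_hmm"))
  expression <- as.matrix(expression)
  cols <- which(model$tracks$mark == mark)
  inds <- model$tracks$individual[cols]
  shared <- intersect(colnames(expression), inds)
  if (length(shared) < 3) stop("need >= 3 shared individuals")
  E <- t(model$emission[, cols[match(shared, inds)], drop = FALSE])  # n x k
  n_win <- as.integer(2 * span / window)
  offs <- -span + (seq_len(n_win) - 0.5) * window  # signed midpoints

  tss_table <- as.data.frame(tss_table)
  tss_table <- tss_table[tss_table$chrom %in% unique(annotation$bins$chrom), ,
                         drop = FALSE]
  genes <- intersect(tss_table$gene, rownames(expression))
  if (length(genes) == 0) stop("no usable genes (TSS on annotated chromosomes)")
  tss_table <- tss_table[match(genes, tss_table$gene), ]

  # genes x states correlation over shared individuals
  gs_r <- stats::cor(t(expression[genes, shared, drop = FALSE]), E)

  bins <- annotation$bins
  chrom_info <- lapply(split(seq_len(nrow(bins)), bins$chrom), function(i)
    list(idx = i, s0 = bins$start[i[1]], n = length(i)))

  sum_r <- numeric(n_win)
  n_r <- integer(n_win)
  for (gi in seq_along(genes)) {
    ci <- chrom_info[[tss_table$chrom[gi]]]
    sgn <- if (identical(tss_table$strand[gi], "-")) -1 else 1
    pos <- tss_table$pos[gi] + sgn * offs
    bin_i <- floor((pos - ci$s0) / 200) + 1
    ok <- bin_i >= 1 & bin_i <= ci$n
    st <- annotation$state[ci$idx[bin_i[ok]]]
    sum_r[ok] <- sum_r[ok] + gs_r[gi, st]
    n_r[ok] <- n_r[ok] + 1L
  }
  out <- data.frame(distance = offs, mean_r = ifelse(n_r > 0, sum_r / n_r, NA),
                    n_genes = n_r)
  attr(out, "gene_state_r") <- gs_r
  out
}

#' Co-expression module eigengenes
#'
#' The eigengene of a module is the first principal-component score of the
#' module's standardized gene-by-individual expression submatrix, with sign
#' fixed so the eigengene correlates positively with the module's mean
#' expression.
#'
#' @param expression genes x individuals matrix (row names = gene ids).
#' @param module_assignments data.frame with columns `gene`, `module`, or a
#'   named vector gene -> module.
#' @return modules x individuals matrix, with per-module variance explained
#'   as attribute `"var_explained"`.
#' @export
module_eigengenes <- function(expression, module_assignments) {
  expression <- as.matrix(expression)
  if (is.data.frame(module_assignments)) {
    mods <- split(module_assignments$gene, module_assignments$module)
  } else {
    mods <- split(names(module_assignments), module_assignments)
  }
  out <- matrix(NA_real_, length(mods), ncol(expression),
                dimnames = list(names(mods), colnames(expression)))
  ve <- stats::setNames(numeric(length(mods)), names(mods))
  for (m in names(mods)) {
    genes <- intersect(mods[[m]], rownames(expression))
    if (length(genes) < 2)
      stop(sprintf("module %s has < 2 genes in the expression matrix", m))
    sub <- expression[genes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0))
      stop(sprintf("module %s contains constant genes", m))
    z <- (sub - rowMeans(sub)) / sds
    sv <- svd(z, nu = 0, nv = 1)
    eig <- sv$v[, 1]
    if (stats::cor(eig, colMeans(z)) < 0) eig <- -eig
    out[m, ] <- eig
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(out, "var_explained") <- ve
  out
}

#' Overlap between expression- and protein-associated genes
#'
#' Fisher's exact test of the overlap between the set of genes whose
#' expression is associated with at least one global pattern and the set
#' whose protein abundance is, within the universe of genes measured on both
#' platforms; additionally counts features associated with at least one
#' common state on both platforms.
#'
#' @param sig_genes,sig_proteins either character vectors of feature ids or
#'   `associate_emissions()` results (significant rows are used, and state
#'   sets derived from them).
#' @param universe feature ids measured on both platforms.
#' @return list with `fisher` (see [fisher_overlap()]) and
#'   `shared_state_count`.
#' @export
gene_protein_overlap <- function(sig_genes, sig_proteins, universe) {
  get_sets <- function(x) {
    if (is.data.frame(x)) {
      sig <- x[x$significant, , drop = FALSE]
      list(ids = unique(sig$feature),
           states = split(sig$state, sig$feature))
    } else {
      list(ids = unique(as.character(x)), states = NULL)
    }
  }
  a <- get_sets(sig_genes); b <- get_sets(sig_proteins)
  fo <- fisher_overlap(a$ids, b$ids, universe)
  shared <- NA_integer_
  if (!is.null(a$states) && !is.null(b$states)) {
    both <- intersect(a$ids, b$ids)
    shared <- sum(vapply(both, function(f)
      length(intersect(a$states[[f]], b$states[[f]])) > 0, logical(1)))
  }
  list(fisher = fo, shared_state_count = shared)
}
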