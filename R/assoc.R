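#' Fast OLS association between phenotype and predictor panels
#'
#' Residualizes phenotypes and predictors against an intercept plus optional
#' covariates, then computes, for every (predictor, phenotype) pair, the OLS
#' slope of phenotype on predictor and its two-sided t-test. Algebraically
#' identical to fitting `lm(y ~ x + covariates)` pair by pair, but runs as
#' three matrix products — the standard trick of eQTL engines.
#'
#' @param Y numeric matrix, individuals x phenotypes.
#' @param X numeric matrix, individuals x predictors.
#' @param covariates optional numeric matrix, individuals x covariates.
#' @return list with matrices `beta`, `t`, `p` (predictors x phenotypes) and
#'   the residual degrees of freedom `df`. Constant predictors or phenotypes
#'   give `NaN` entries.
#' @export
fast_lm_assoc <- function(Y, X, covariates = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X disagree on the number of individuals")
  C <- cbind(rep(1, n), covariates)
  qc <- qr(C)
  if (qc$rank < ncol(C)) stop("singular covariate design")
  df <- n - qc$rank - 1L
  if (df < 1) stop("not enough individuals for the design")
  Yr <- qr.resid(qc, Y)
  Xr <- qr.resid(qc, X)
  sx2 <- colSums(Xr^2)
  sy2 <- colSums(Yr^2)
  cross <- crossprod(Xr, Yr)
  beta <- cross / sx2
  r <- cross / sqrt(outer(sx2, sy2))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = beta, t = tstat, p = p, df = df)
}

#' Genotype dosage matrix
#'
#' @param dosages integer matrix, SNPs x individuals, values in {0, 1, 2};
#'   column names are individual ids.
#' @param snps data.frame with columns chrom, pos, id (and optionally
#'   ref/alt), one row per SNP.
#' @return object of class `genotype_matrix` with derived per-SNP minor
#'   allele frequency in `$maf`.
#' @export
genotype_matrix <- function(dosages, snps) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% 0:2)) stop("dosages must be in {0, 1, 2}")
  if (anyNA(dosages)) stop("missing dosages are not supported")
  storage.mode(dosages) <- "integer"
  snps <- as.data.frame(snps)
  stopifnot(all(c("chrom", "pos", "id") %in% names(snps)),
            nrow(snps) == nrow(dosages))
  af <- rowMeans(dosages) / 2
  structure(list(dosages = dosages, snps = snps, maf = pmin(af, 1 - af)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals, MAF in [%.3f, %.3f]\n",
              nrow(x$dosages), ncol(x$dosages), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Top genotype principal components
#'
#' PC scores of the standardized dosage matrix (individuals x SNPs), the
#' usual ancestry covariates of genetic association tests.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_pcs number of components (default 20, capped by rank).
#' @return individuals x n_pcs score matrix.
#' @export
genotype_pcs <- function(genotypes, n_pcs = 20L) {
  g <- t(genotypes$dosages)
  keep <- apply(g, 2, stats::sd) > 0
  g <- scale(g[, keep, drop = FALSE])
  sv <- svd(g, nu = min(n_pcs, nrow(g) - 1L), nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Read/write genotype dosages
#'
#' `write_genotypes_tsv` writes the SNP x individual dosage table with SNP
#' metadata columns; `write_vcf_minimal` writes a minimal VCF with GT fields
#' only; `read_genotypes_tsv`/`read_vcf_minimal` invert them.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @return the path (writers) or a [genotype_matrix()] (readers).
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- cbind(genotypes$snps[, c("chrom", "pos", "id")],
              as.data.frame(genotypes$dosages))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, c("chrom", "pos", "id")]
  meta$ref <- "A"; meta$alt <- "G"
  genotype_matrix(as.matrix(df[, -(1:3), drop = FALSE]), meta)
}

#' @rdname write_genotypes_tsv
#' @export
write_vcf_minimal <- function(genotypes, path) {
  gt <- c("0/0", "0/1", "1/1")[genotypes$dosages + 1L]
  gt <- matrix(gt, nrow = nrow(genotypes$dosages))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(genotypes$dosages)),
                     collapse = "\t")), con)
  s <- genotypes$snps
  body <- cbind(s$chrom, s$pos, s$id,
                if (is.null(s$ref)) "A" else s$ref,
                if (is.null(s$alt)) "G" else s$alt,
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1) stop("missing #CHROM header line")
  cols <- strsplit(hdr, "\t")[[1]]
  inds <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- do.call(rbind, strsplit(body, "\t"))
  dos <- matrix(match(fields[, -(1:9), drop = FALSE],
                      c("0/0", "0/1", "1/1")) - 1L,
                nrow = nrow(fields), dimnames = list(NULL, inds))
  if (anyNA(dos)) stop("unsupported genotype codes (GT must be 0/0, 0/1, 1/1)")
  genotype_matrix(dos, data.frame(chrom = fields[, 1],
                                  pos = as.numeric(fields[, 2]),
                                  id = fields[, 3], ref = fields[, 4],
                                  alt = fields[, 5],
                                  stringsAsFactors = FALSE))
}
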