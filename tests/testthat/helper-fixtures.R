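# Shared fixture builders; everything is generated in code.

# Small aligned study with D platforms over identical genes/samples.
toy_study <- function(n_genes = 20L, n_samples = 30L, D = 2L, seed = 1L,
                      labels = NULL) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  mats <- lapply(seq_len(D), function(d) {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(genes, samples))
    genomic_matrix(m, paste0("P", d))
  })
  if (is.null(labels)) {
    labels <- rep(c(0L, 1L), length.out = n_samples)
  }
  build_study(mats, phenotype_binary(samples, labels))
}

# Study where platforms measure different (overlapping) gene subsets.
ragged_study <- function(seed = 7L) {
  set.seed(seed)
  samples <- sprintf("s%02d", 1:20)
  mk <- function(genes, id) {
    m <- matrix(rnorm(length(genes) * 20), length(genes), 20,
                dimnames = list(genes, samples))
    genomic_matrix(m, id)
  }
  build_study(
    list(mk(c("a", "b", "c", "d"), "E1"),
         mk(c("b", "c", "d", "e"), "E2"),
         mk(c("c", "d", "e", "f"), "C1")),
    phenotype_binary(samples, rep(0:1, each = 10)))
}

# Direct likelihood-maximization oracle for the logistic deviance
# (independent of IRLS): minimizes the negative log-likelihood with a
# general-purpose optimizer on the raw predictor scale.
oracle_logistic_deviance <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  opt <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  null <- -2 * (sum(y) * log(mean(y)) + sum(1 - y) * log(1 - mean(y)))
  list(null_deviance = null, residual_deviance = 2 * opt$value,
       score = null - 2 * opt$value)
}

# Brute-force one-sided Mann-Whitney p-value by enumerating every
# assignment of the pooled scores to the in-set positions.
enumerate_mw_p <- function(inset, outset) {
  pooled <- c(inset, outset)
  n1 <- length(inset)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  U_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(U_all >= U_obs - 1e-9)
}

backbone_gene_ids_for_test <- function(n) sprintf("g%05d", seq_len(n))
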