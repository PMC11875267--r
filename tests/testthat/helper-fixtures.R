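# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  # 4 CpGs x 2 samples; S2 uncovered at the third site
  cpg_count_matrix(
    chrom = rep("chr1", 4), pos = c(100L, 120L, 140L, 400L),
    meth = cbind(S1 = c(3L, 1L, 0L, 5L), S2 = c(8L, 2L, 0L, 0L)),
    total = cbind(S1 = c(10L, 10L, 5L, 10L), S2 = c(10L, 4L, 0L, 2L)),
    samples = c("S1", "S2"))
}

write_counts_file <- function(df, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(df$chrom, df$pos, df$meth, df$total, sep = "\t")), path)
  path
}

two_group_labels <- function(n_per = 5L) rep(c(0L, 1L), each = n_per)

# Independent beta-binomial log-likelihood maximizer used as an oracle:
# same likelihood, different optimizer (nlminb) and code path.
oracle_bb_loglik <- function(par, y, n, X) {
  mu <- plogis(drop(X %*% par[-length(par)]))
  rho <- plogis(par[length(par)])
  t <- (1 - rho) / rho
  sum(lbeta(y + mu * t, n - y + (1 - mu) * t) - lbeta(mu * t, (1 - mu) * t))
}

oracle_bb_fit <- function(y, n, X) {
  nlminb(c(rep(0, ncol(X)), qlogis(0.1)),
         function(p) -oracle_bb_loglik(p, y, n, X))
}

# Hand-computed two-group log-rank statistic (O-E and hypergeometric
# variance accumulated over distinct event times).
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) - 1L
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
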