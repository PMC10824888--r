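# deterministic in-code fixtures for the tests

# random report-level frame: every report gets >= 1 ADR
make_reports <- function(n = 300, drugs = c("D", "E", "F"),
                         adrs = c("A", "B", "C", "G"), seed = 1,
                         p_drug = 0.3, p_adr = 0.25) {
  set.seed(seed)
  dmat <- matrix(rbinom(n * length(drugs), 1, p_drug), n)
  amat <- matrix(rbinom(n * length(adrs), 1, p_adr), n)
  none <- rowSums(amat) == 0
  amat[cbind(which(none),
             sample.int(length(adrs), sum(none), replace = TRUE))] <- 1L
  cols <- c(list(seq_len(n)),
            lapply(seq_along(drugs), function(j) dmat[, j]),
            lapply(seq_along(adrs), function(j) amat[, j]))
  tibble::as_tibble(
    stats::setNames(cols, c("report_id", paste0("drug:", drugs),
                            paste0("adr:", adrs))))
}

# counts frame simulated directly from the Poisson mixed model:
# log rate = b0 + (beta + b1) * x per ADR, random effects N(0, gamma)
make_glmm_counts <- function(J = 50, beta0 = log(5e-4), beta = log(2),
                             gamma0 = 0.25, gamma1 = 0.25,
                             d1 = 1e4, d0 = 1e6, seed = 1) {
  set.seed(seed)
  b0 <- rnorm(J, 0, sqrt(gamma0))
  b1 <- rnorm(J, 0, sqrt(gamma1))
  lam0 <- exp(beta0 + b0) * d0
  lam1 <- exp(beta0 + b0 + beta + b1) * d1
  adr <- sprintf("adr_%03d", seq_len(J))
  out <- tibble::tibble(
    stratum = rep(c("unexposed", "exposed"), each = J),
    adr = c(adr, adr),
    count = c(rpois(J, lam0), rpois(J, lam1)),
    denominator = rep(c(d0, d1), each = J),
    drug1 = rep(c(0L, 1L), each = J)
  )
  class(out) <- c("adr_counts", class(out))
  attr(out, "truth") <- list(beta = beta, gamma0 = gamma0, gamma1 = gamma1,
                             b0 = b0, b1 = b1)
  out
}

# dense REML criterion: -2 restricted log-likelihood of
# z = X beta + Z b + e, b ~ N(0, gamma I), e ~ N(0, diag(1/w))
dense_reml_crit <- function(gamma, z, w, X, Zd) {
  V <- gamma * tcrossprod(Zd) + diag(1 / w)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  beta <- solve(XVX, t(X) %*% Vi %*% z)
  r <- z - X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XVX)$modulus +
               t(r) %*% Vi %*% r)
}
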