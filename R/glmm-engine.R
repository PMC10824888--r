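#' Specify a generalized linear mixed model for screening
#'
#' Defines the count response, family/link, fixed design and random-effect
#' blocks of a Poisson (log link, offset) or binomial (logit link, trials)
#' mixed model.  Each random block is a covariate whose per-group (per-ADR)
#' coefficients share one variance component; blocks are mutually independent
#' and independent across groups.  A per-ADR free variance (one component per
#' group) is not identifiable from a single observation per group per stratum,
#' which is why blocks share their variance.
#'
#' @param y Integer count response, one element per (stratum, group) cell.
#' @param X Fixed-effects design matrix (rows match `y`); must have full
#'   column rank.
#' @param family `"poisson"` (log link) or `"binomial"` (logit link).
#' @param offset For the Poisson family, the log-denominator offset vector.
#' @param trials For the binomial family, the number of trials per row.
#' @param random Named list of numeric covariate vectors (length of `y`); each
#'   defines one random block with design `Z_k[i, j] = cov_k[i] * 1(group_i = j)`.
#' @param group Factor (or coercible) giving the grouping level -- the ADR --
#'   of each row.
#' @param scale_fixed Keep the residual scale of the working model fixed at 1
#'   (the exact-Poisson/binomial assumption, default) or estimate it.
#' @return An object of class `glmm_spec`.
#' @export
glmm_spec <- function(y, X, family = c("poisson", "binomial"),
                      offset = NULL, trials = NULL,
                      random = list(), group, scale_fixed = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(group) == n)
  if (family == "poisson") {
    if (is.null(offset)) stop("poisson spec needs an offset", call. = FALSE)
    stopifnot(length(offset) == n)
    trials <- NULL
  } else {
    if (is.null(trials)) stop("binomial spec needs trials", call. = FALSE)
    stopifnot(length(trials) == n, all(trials > 0), all(y <= trials))
    offset <- NULL
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("response must be non-negative counts", call. = FALSE)
  }
  group <- droplevels(as.factor(group))
  if (qr(X)$rank < ncol(X)) {
    stop("fixed design is rank deficient", call. = FALSE)
  }
  if (length(random) > 0) {
    if (is.null(names(random)) || any(names(random) == "")) {
      stop("random blocks must be named", call. = FALSE)
    }
    if (anyDuplicated(names(random))) {
      stop("random block (variance) labels must be distinct", call. = FALSE)
    }
    for (v in random) stopifnot(length(v) == n)
  }
  structure(
    list(y = as.numeric(y), X = X, family = family,
         offset = offset, trials = trials,
         random = random, group = group, scale_fixed = scale_fixed),
    class = "glmm_spec"
  )
}

# re-factorize a sparse symmetric matrix reusing a symbolic Cholesky analysis
update_chmfactor <- local({
  fn <- NULL
  function(factor, C) {
    if (is.null(fn)) {
      fn <<- methods::getMethod("update", "CHMfactor",
                                where = asNamespace("Matrix"))
    }
    fn(factor, C)
  }
})

# Sparse block-major random-effects design: columns are
# (block 1: level 1..J), (block 2: level 1..J), ...
build_Z <- function(spec) {
  n <- length(spec$y)
  J <- nlevels(spec$group)
  K <- length(spec$random)
  if (K == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, 0)))
  }
  gi <- as.integer(spec$group)
  i <- rep(seq_len(n), K)
  j <- unlist(lapply(seq_len(K), function(k) (k - 1L) * J + gi))
  x <- unlist(spec$random, use.names = FALSE)
  keep <- x != 0
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(n, K * J))
}

#' Linearize a GLMM around a linear predictor
#'
#' One pseudo-likelihood step: expands the mean model about `eta` and returns
#' the working response and working weights of the induced weighted linear
#' mixed model.  For Poisson/log with offset `o`: `mu = exp(eta)`,
#' `z = (eta - o) + (y - mu)/mu`, `w = mu`.  For binomial/logit with `m`
#' trials: `p = logistic(eta)`, `z = eta + (y/m - p)/(p(1-p))`,
#' `w = m p (1-p)`.  Means (and `p(1-p)`) are floored at `1e-10` to keep the
#' weights positive; a warning is raised if flooring occurs.
#'
#' @param spec A [glmm_spec()].
#' @param eta Current full linear predictor (including offset for Poisson).
#' @return A list with elements `z` (working response for the `X beta + Z b`
#'   part) and `w` (working weights).
#' @export
linearize <- function(spec, eta) {
  stopifnot(all(is.finite(eta)))
  eps <- 1e-10
  if (spec$family == "poisson") {
    mu <- exp(eta)
    if (any(mu < eps)) {
      warning("fitted means floored at 1e-10 during linearization")
      mu <- pmax(mu, eps)
    }
    o <- spec$offset
    list(z = (eta - o) + (spec$y - mu) / mu, w = mu)
  } else {
    p <- stats::plogis(eta)
    v <- p * (1 - p)
    if (any(v < eps)) {
      warning("fitted variances floored at 1e-10 during linearization")
      v <- pmax(v, eps)
    }
    m <- spec$trials
    list(z = eta + (spec$y / m - p) / v, w = m * v)
  }
}

#' Fit the working linear mixed model by REML
#'
#' Estimates the variance components of
#' `z = X beta + sum_k Z_k b_k + e`, `e ~ (0, phi W^{-1})`, by restricted
#' maximum likelihood, then solves the mixed-model equations at the optimum
#' for the fixed effects and BLUPs.  The prediction covariance of
#' `(beta_hat, b_hat - b)` is the inverse of the mixed-model-equation
#' coefficient matrix, factored sparsely and materialised on demand.
#'
#' The REML objective (up to an additive constant), with
#' `C` the MME coefficient matrix, `G = blockdiag(gamma_k I)`, and residual
#' covariance `phi W^{-1}`, is
#' `sum_k J log gamma_k + n log phi - sum log w + log|C| + r'Wr/phi +
#' b'G^{-1}b`, minimised over `log gamma` (and `log phi` unless the scale is
#' fixed at 1) by bound-constrained quasi-Newton with `gamma` clamped at
#' `1e-10`.
#'
#' @param z,w Working response and weights.
#' @param X Fixed design matrix.
#' @param Z Sparse random-effects design (block-major columns).
#' @param blocks Character vector of block labels; `J` levels per block.
#' @param J Number of grouping levels per block.
#' @param gamma_init Starting variance components (one per block).
#' @param scale_fixed Fix the residual scale at 1.
#' @param reltol Convergence tolerance of the inner optimizer.
#' @return A list with `beta`, `blups` (matrix `J x K`), `gamma`, `phi`,
#'   `objective`, `chol` (factor of the MME matrix), bookkeeping needed for
#'   prediction, and the optimizer trace.
#' @export
reml_fit_working <- function(z, w, X, Z, blocks, J, gamma_init,
                             scale_fixed = TRUE, reltol = 1e-10) {
  n <- length(z); p <- ncol(X); K <- length(blocks); q <- ncol(Z)
  stopifnot(q == K * J, length(gamma_init) == K)
  sw <- sqrt(w)
  Xw <- X * sw
  Zw <- Z * sw
  ZtWZ <- Matrix::crossprod(Zw)
  ZtWX <- Matrix::crossprod(Zw, Xw)
  XtWX <- crossprod(Xw)
  zw <- sw * z
  rhs_full <- c(as.numeric(Matrix::crossprod(Zw, zw)), crossprod(Xw, zw))
  sumlogw <- sum(log(w))

  # aliasing check on the weighted fixed design
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("aliased fixed-effect column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # assemble the MME matrix once; per evaluation only the G^{-1} diagonal
  # (and the 1/phi scale) changes
  Cbase <- methods::as(Matrix::forceSymmetric(rbind(
    cbind(ZtWZ, ZtWX),
    cbind(Matrix::t(ZtWX), XtWX)
  )), "CsparseMatrix")
  # ensure all diagonal entries are structurally present so that adding a
  # Diagonal() keeps the sparsity pattern of the symbolic factorization
  Cbase <- Cbase + Matrix::Diagonal(n = q + p, x = 0)
  # locate the diagonal entries of the random-effect block inside @x (upper
  # triangle storage: the diagonal is the last entry of each column slab)
  diag_idx <- if (q > 0) Cbase@p[2:(q + 1)] else integer(0)
  stopifnot(all(Cbase@i[diag_idx] == seq_len(q) - 1L))

  Cpattern <- NULL
  assemble <- function(gamma, phi) {
    ginv <- rep(1 / gamma, each = J)
    C <- Cbase
    x <- C@x / phi
    x[diag_idx] <- x[diag_idx] + ginv
    C@x <- x
    C
  }

  solve_at <- function(gamma, phi) {
    C <- assemble(gamma, phi)
    ch <- if (is.null(Cpattern)) {
      Cpattern <<- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
      Cpattern
    } else {
      update_chmfactor(Cpattern, C)
    }
    sol <- as.numeric(Matrix::solve(ch, rhs_full / phi, system = "A"))
    list(C = C, ch = ch, b = sol[seq_len(q)], beta = sol[q + seq_len(p)])
  }

  objective <- function(gamma, phi) {
    s <- solve_at(gamma, phi)
    r <- z - as.numeric(X %*% s$beta) - as.numeric(Z %*% s$b)
    quad <- sum(w * r^2) / phi + sum(s$b^2 / rep(gamma, each = J))
    logdetC <- 2 * as.numeric(Matrix::determinant(s$ch, sqrt = TRUE)$modulus)
    J * sum(log(gamma)) + n * log(phi) - sumlogw + logdetC + quad
  }

  trace_env <- new.env()
  trace_env$par <- NULL
  lb <- log(1e-10)
  fn <- function(par) {
    gamma <- exp(par[seq_len(K)])
    phi <- if (scale_fixed) 1 else exp(par[K + 1])
    val <- objective(gamma, phi)
    trace_env$par <- rbind(trace_env$par, c(gamma, phi, val))
    val
  }
  par0 <- log(pmax(gamma_init, 1e-10))
  if (!scale_fixed) par0 <- c(par0, 0)
  if (K == 0 && scale_fixed) {
    s <- solve_at(numeric(0), 1)
    opt <- list(convergence = 0, value = objective(numeric(0), 1))
    gamma_hat <- numeric(0); phi_hat <- 1
  } else {
    opt <- stats::optim(par0, fn, method = "L-BFGS-B",
                        lower = lb, upper = log(1e10),
                        control = list(factr = reltol / 1e-15,
                                       pgtol = 1e-12,
                                       ndeps = rep(1e-5, length(par0)),
                                       maxit = 200))
    if (opt$convergence != 0 && opt$convergence != 52) {
      cond <- simpleError(paste0(
        "REML optimizer failed to converge (code ", opt$convergence, "): ",
        opt$message))
      cond$trace <- trace_env$par
      stop(cond)
    }
    gamma_hat <- exp(opt$par[seq_len(K)])
    phi_hat <- if (scale_fixed) 1 else exp(opt$par[K + 1])
    s <- solve_at(gamma_hat, phi_hat)
  }
  # a block pinned at the lower bound means gamma = 0: zero out its BLUPs
  pinned <- gamma_hat <= 1e-10 * (1 + 1e-6)
  b <- s$b
  if (any(pinned)) {
    for (k in which(pinned)) b[(k - 1L) * J + seq_len(J)] <- 0
  }
  list(
    beta = stats::setNames(as.numeric(s$beta), colnames(X)),
    blups = matrix(b, nrow = J, ncol = K,
                   dimnames = list(NULL, blocks)),
    gamma = stats::setNames(as.numeric(gamma_hat), blocks),
    phi = phi_hat,
    objective = opt$value,
    chol = s$ch, C = s$C, q = q, p = p, J = J, K = K,
    trace = trace_env$par
  )
}

#' Control parameters for the doubly iterative fit
#'
#' @param outer_tol Relative-change tolerance on `(beta, gamma)` between outer
#'   linearizations (default 1e-4; the pseudo-likelihood alternation has a small limit cycle, so
#   tolerances below ~1e-5 are not attainable or meaningful).
#' @param max_outer Maximum outer iterations (default 100).
#' @param inner_tol REML optimizer tolerance (default 1e-10).
#' @param gamma_init Starting value for every variance component (default 0.1).
#' @export
glmm_control <- function(outer_tol = 1e-4, max_outer = 100,
                         inner_tol = 1e-10, gamma_init = 0.1) {
  list(outer_tol = outer_tol, max_outer = max_outer,
       inner_tol = inner_tol, gamma_init = gamma_init)
}

#' Fit a screening GLMM by restricted pseudo-likelihood
#'
#' Alternates [linearize()] (expansion about the current fixed effects and
#' BLUPs) with [reml_fit_working()] until the fixed effects and variance
#' components stabilise.  Fixed effects start at the fixed-effect-only GLM
#' solution; variance components start at `gamma_init`.  A variance component
#' estimated at its lower bound (effectively zero) is not an error; failure of
#' the outer loop to stabilise is, and the error carries the iteration trace.
#'
#' @param spec A [glmm_spec()].
#' @param control A [glmm_control()] list.
#' @return An object of class `adr_glmm`: fixed effects with covariance,
#'   variance components, per-group BLUPs, the factored mixed-model-equation
#'   matrix for prediction variances, convergence state and the per-iteration
#'   variance-component trace.
#' @export
fit_glmm <- function(spec, control = glmm_control()) {
  X <- spec$X
  n <- length(spec$y)
  J <- nlevels(spec$group)
  K <- length(spec$random)
  Z <- build_Z(spec)

  fam <- if (spec$family == "poisson") stats::poisson() else stats::binomial()
  init <- if (spec$family == "poisson") {
    stats::glm.fit(X, spec$y, family = fam, offset = spec$offset)
  } else {
    stats::glm.fit(X, spec$y / spec$trials, weights = spec$trials,
                   family = fam)
  }
  beta <- init$coefficients
  b <- rep(0, ncol(Z))
  gamma <- rep(control$gamma_init, K)
  eta <- as.numeric(X %*% beta) + as.numeric(Z %*% b) +
    if (spec$family == "poisson") spec$offset else 0

  trace <- NULL
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(control$max_outer)) {
    zw <- linearize(spec, eta)
    fit <- reml_fit_working(zw$z, zw$w, X, Z, names(spec$random), J,
                            gamma_init = gamma,
                            scale_fixed = spec$scale_fixed,
                            reltol = control$inner_tol)
    new_beta <- fit$beta
    new_gamma <- fit$gamma
    trace <- rbind(trace, c(iter = it, new_gamma,
                            phi = fit$phi, objective = fit$objective))
    delta <- max(abs(c(new_beta, new_gamma) - c(beta, gamma)) /
                   (abs(c(beta, gamma)) + 1e-4))
    beta <- new_beta
    gamma <- new_gamma
    b <- as.numeric(fit$blups)
    eta <- as.numeric(X %*% beta) + as.numeric(Z %*% b) +
      if (spec$family == "poisson") spec$offset else 0
    if (it > 1 && delta < control$outer_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- simpleError(paste0(
      "outer pseudo-likelihood loop did not converge in ",
      control$max_outer, " iterations"))
    cond$trace <- trace
    stop(cond)
  }

  beta_cov <- joint_cov_block(fit, "beta")
  structure(
    list(
      beta = beta,
      beta_cov = beta_cov,
      gamma = gamma,
      phi = fit$phi,
      blups = tibble::tibble(
        group = rep(levels(spec$group), K),
        block = rep(names(spec$random), each = J),
        blup = as.numeric(fit$blups)
      ),
      working_fit = fit,
      group_levels = levels(spec$group),
      blocks = names(spec$random),
      family = spec$family,
      converged = converged,
      n_outer_iter = it,
      pseudo_trace = trace,
      nobs = n
    ),
    class = "adr_glmm"
  )
}

# extract blocks of the inverse MME coefficient matrix
joint_cov_block <- function(fit, what = c("beta", "full")) {
  what <- match.arg(what)
  qp <- fit$q + fit$p
  if (what == "beta") {
    E <- matrix(0, qp, fit$p)
    E[fit$q + seq_len(fit$p), ] <- diag(fit$p)
    V <- as.matrix(Matrix::solve(fit$ch, E, system = "A"))
    out <- crossprod(E, V)
  } else {
    out <- as.matrix(Matrix::solve(fit$ch, diag(qp), system = "A"))
  }
  (out + t(out)) / 2
}

#' Joint prediction covariance of the fitted coefficients
#'
#' Returns the full inverse of the mixed-model-equation coefficient matrix:
#' the covariance of `(beta_hat, b_hat - b)`, ordered fixed effects first,
#' then random blocks (block-major, `J` levels each).
#'
#' @param fit An `adr_glmm` fit.
#' @return A dense symmetric matrix.
#' @export
joint_vcov <- function(fit) {
  w <- fit$working_fit
  full <- joint_cov_block(w, "full")
  ord <- c(w$q + seq_len(w$p), seq_len(w$q))
  out <- full[ord, ord]
  dimnames(out) <- NULL
  out
}

#' Estimate and standard error of a linear combination of coefficients
#'
#' Computes `l_f' beta_hat + l_r' b_hat` and its prediction standard error
#' `sqrt([l_f; l_r]' C^{-1} [l_f; l_r])` from the factored mixed-model
#' equations -- the quantity behind ADR-specific PRR/ROR intervals such as
#' `beta_i + b_ij`.  Columns of matrix inputs are treated as separate
#' combinations.
#'
#' @param fit An `adr_glmm` fit.
#' @param coeffs_fixed Numeric vector (length `p`) or `p x m` matrix.
#' @param coeffs_random Numeric vector (length `q = K*J`, block-major) or
#'   `q x m` matrix.
#' @return A tibble with columns `estimate` and `se`.
#' @export
predict_linear_combo <- function(fit, coeffs_fixed, coeffs_random) {
  w <- fit$working_fit
  lf <- as.matrix(coeffs_fixed)
  lr <- as.matrix(coeffs_random)
  if (nrow(lf) != w$p || nrow(lr) != w$q || ncol(lf) != ncol(lr)) {
    stop("coefficient vectors do not conform to the fit dimensions",
         call. = FALSE)
  }
  L <- rbind(lr, lf)  # internal order: random first
  est <- as.numeric(crossprod(lf, fit$beta)) +
    as.numeric(crossprod(lr, as.numeric(w$blups)))
  V <- Matrix::solve(w$ch, L, system = "A")
  se2 <- colSums(L * as.matrix(V))
  tibble::tibble(estimate = est, se = sqrt(pmax(se2, 0)))
}

#' @exportS3Method base::print
print.adr_glmm <- function(x, ...) {
  cat("Generalized linear mixed model (restricted pseudo-likelihood)\n")
  cat("family:", x$family, " groups:", length(x$group_levels),
      " outer iterations:", x$n_outer_iter, "\n")
  cat("fixed effects:\n")
  print(round(x$beta, 6))
  cat("variance components:\n")
  print(round(x$gamma, 6))
  invisible(x)
}

#' Serialize a fit summary to JSON
#'
#' @param fit An `adr_glmm` fit.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @export
glmm_to_json <- function(fit, path = NULL) {
  obj <- list(
    family = fit$family,
    beta = as.list(fit$beta),
    gamma = as.list(fit$gamma),
    phi = fit$phi,
    converged = fit$converged,
    n_outer_iter = fit$n_outer_iter,
    trace = apply(fit$pseudo_trace, 1, as.list),
    blups = fit$blups
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
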