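# REML engine for pedigree animal models, built on sparse mixed-model
# equations (MME). For y = Xb + Zu + e with u ~ N(0, G), e ~ N(0, R), the
# restricted log-likelihood is evaluated through the MME coefficient matrix
# C = W'R^-1 W + diag(0, G^-1), W = [X Z]:
#   -2 lR = (n - p) log 2pi + log|R| + log|G| + log|C| - log|X'X| + y'Py
# with y'Py = y'R^-1 y - rhs' C^-1 rhs, rhs = W'R^-1 y. The -log|X'X| term
# (Harville's convention) makes lR invariant to the fixed-effect coding.
# C is assembled each iteration as a linear combination of precomputed
# sparse components with a fixed sparsity pattern, so the symbolic Cholesky
# factorisation is done once and only the numeric factor is updated.

# --- sparse component machinery ---------------------------------------

as_dsc <- function(m) {
  methods::as(methods::as(Matrix::forceSymmetric(m), "CsparseMatrix"),
              "dMatrix")
}

# union pattern + map of component x-slots into it
component_system <- function(comps) {
  comps <- lapply(comps, as_dsc)
  absx <- lapply(comps, function(m) { m@x <- abs(m@x) + 1; m })
  template <- Reduce(`+`, absx)
  nu <- length(template@x)
  tkey <- key_of(template)
  map <- matrix(0, nrow = nu, ncol = length(comps))
  for (k in seq_along(comps)) {
    m <- comps[[k]]
    idx <- match(key_of(m), tkey)
    map[idx, k] <- m@x
  }
  list(template = template, map = map)
}

key_of <- function(m) {
  # (col, row) key for dsCMatrix entries
  p <- m@p
  j <- rep.int(seq_len(length(p) - 1L), diff(p))
  as.numeric(j) * nrow(m) + m@i
}

assemble <- function(sys, coefs) {
  m <- sys$template
  m@x <- as.numeric(sys$map %*% coefs)
  m
}

chol_logdet_solve <- function(chol_template, Cmat, rhs) {
  # non-positive-definite trial points raise an error handled by the
  # caller; CHOLMOD's accompanying warning is just noise
  ch <- suppressWarnings(Matrix::update(chol_template, Cmat))
  ldet <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                             sqrt = TRUE)$modulus)
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  # one step of iterative refinement keeps the quadratic form accurate
  # enough for fine optimum location
  resid <- rhs - as.numeric(Cmat %*% sol)
  sol <- sol + as.numeric(Matrix::solve(ch, resid, system = "A"))
  list(ldet = ldet, sol = sol)
}

# symbolic + first numeric factorisation of the union pattern; a diagonal
# shift makes the pattern instance positive definite (the diagonal is
# always structurally present in the MME coefficient matrix)
initial_cholesky <- function(sys) {
  tt <- sys$template
  shifted <- tt + Matrix::Diagonal(nrow(tt), 2 * sum(abs(tt@x)))
  if (length(shifted@x) != length(tt@x))
    stop("internal error: MME diagonal not structurally complete")
  Matrix::Cholesky(shifted, LDL = FALSE, perm = TRUE)
}

# embed a symmetric sparse block on the diagonal of a pdim x pdim matrix
embed_diag_block <- function(m, offset, pdim) {
  t3 <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = t3@i + 1L + offset, j = t3@j + 1L + offset,
                       x = t3@x, dims = c(pdim, pdim), symmetric = FALSE)
}

# embed m at (roff, coff) and its transpose at (coff, roff)
embed_cross_block <- function(m, roff, coff, pdim) {
  t3 <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = c(t3@i + 1L + roff, t3@j + 1L + coff),
                       j = c(t3@j + 1L + coff, t3@i + 1L + roff),
                       x = c(t3@x, t3@x), dims = c(pdim, pdim),
                       symmetric = FALSE)
}

logdet_dense <- function(M) {
  as.numeric(determinant(M, logarithm = TRUE)$modulus)
}

# finite-difference Hessian (central), for observed information at optimum
fd_hessian <- function(fn, x, eps = NULL) {
  k <- length(x)
  if (is.null(eps)) eps <- pmax(abs(x), 1) * 1e-3
  H <- matrix(NA_real_, k, k)
  f0 <- fn(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- eps[i]; ej[j] <- eps[j]
      if (i == j) {
        H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / eps[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(x + ei + ej) - fn(x + ei - ej) -
             fn(x - ei + ej) + fn(x - ei - ej)) / (4 * eps[i] * eps[j])
      }
    }
  }
  H
}

fd_gradient <- function(fn, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    ei <- numeric(length(x)); ei[i] <- eps
    (fn(x + ei) - fn(x - ei)) / (2 * eps)
  }, 0)
}

# one or two guarded Newton steps to polish a quasi-Newton optimum past
# the precision of its finite-difference gradients
newton_polish <- function(fn, x, f0, lower, upper, steps = 2L) {
  for (s in seq_len(steps)) {
    if (any(x < lower + 0.5) || any(x > upper - 0.5)) return(list(par = x, objective = f0))
    g <- fd_gradient(fn, x)
    H <- tryCatch(fd_hessian(fn, x), error = function(e) NULL)
    if (is.null(H)) return(list(par = x, objective = f0))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(list(par = x, objective = f0))
    # the quadratic model can over- or under-shoot at this resolution, so
    # line-search along the Newton direction and keep the best point
    best <- list(par = x, objective = f0)
    for (sc in c(1, 0.5, 0.25, 0.1, 0.05, 0.02)) {
      cand <- x - sc * step
      fc <- fn(cand)
      if (is.finite(fc) && fc < best$objective)
        best <- list(par = cand, objective = fc)
    }
    if (best$objective >= f0) return(list(par = x, objective = f0))
    x <- best$par; f0 <- best$objective
  }
  list(par = x, objective = f0)
}

fd_jacobian <- function(fn, x, eps = NULL) {
  if (is.null(eps)) eps <- pmax(abs(x), 1) * 1e-5
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (i in seq_along(x)) {
    ei <- numeric(length(x)); ei[i] <- eps[i]
    J[, i] <- (fn(x + ei) - fn(x - ei)) / (2 * eps[i])
  }
  J
}

# --- univariate REML ---------------------------------------------------

#' Univariate REML animal model
#'
#' Maximises the restricted log-likelihood of
#' \deqn{y \sim N(Xb,\; Z_1 A Z_1' \sigma_a^2 + Z_2 Z_2' \sigma_c^2 +
#'   I \sigma_e^2)}
#' over non-negative variance components, where A is the numerator
#' relationship matrix, Z1 maps records to animals and Z2 maps records to
#' full-sib families (the common-environment/hapa effect). Variances are
#' optimised on the log scale with a quasi-Newton method; the likelihood is
#' evaluated through sparse mixed-model equations. Heritability
#' \eqn{h^2 = \sigma_a^2/\sigma_p^2} and the common-environment ratio
#' \eqn{c^2 = \sigma_c^2/\sigma_p^2} are reported with delta-method
#' standard errors from the inverse observed information.
#'
#' @param bundle a \code{\link{build_design}} bundle.
#' @param random random terms to fit; defaults to the bundle's spec. Use
#'   e.g. \code{"additive"} alone for the reduced model of a likelihood
#'   ratio test on the hapa effect.
#' @param options list: \code{max_iter} (500), \code{rel_tol} (1e-8),
#'   \code{se} (TRUE to compute standard errors), \code{start} (optional
#'   named vector of starting variances).
#' @return An object of class \code{reml_uni} with elements
#'   \code{sigma_a2}, \code{sigma_c2}, \code{sigma_e2}, \code{sigma_p2},
#'   \code{h2}, \code{c2}, \code{se} (named vector), \code{loglik},
#'   \code{converged}, \code{boundary}, \code{n_used}.
#' @export
reml_univariate <- function(bundle, random = NULL, options = list()) {
  stopifnot(inherits(bundle, "design_bundle"))
  opt <- utils::modifyList(list(max_iter = 500L, rel_tol = 1e-8, se = TRUE,
                                start = NULL), options)
  if (is.null(random)) random <- bundle$spec$random
  use_a <- "additive" %in% random
  use_c <- "common_env" %in% random
  y <- bundle$y; X <- bundle$X
  n <- length(y); p <- ncol(X)
  if (n <= p)
    stop("fewer records than fixed-effect columns", call. = FALSE)
  qa <- ncol(bundle$Z1); qc <- ncol(bundle$Z2)
  W <- X
  if (use_a) W <- methods::cbind2(W, bundle$Z1)
  if (use_c) W <- methods::cbind2(W, bundle$Z2)
  W <- methods::as(W, "CsparseMatrix")
  pdim <- ncol(W)
  WtW <- Matrix::crossprod(W)
  Wty <- as.numeric(Matrix::crossprod(W, y))
  ldetXtX <- logdet_dense(crossprod(X))
  comps <- list(WtW)
  off <- p
  if (use_a) {
    comps <- c(comps, list(embed_diag_block(bundle$ainv, off, pdim)))
    off <- off + qa
  }
  if (use_c)
    comps <- c(comps, list(embed_diag_block(Matrix::Diagonal(qc), off, pdim)))
  sys <- component_system(comps)
  chol0 <- initial_cholesky(sys)
  logdetA <- attr(bundle$ainv, "logdet")
  vary <- stats::var(stats::lm.fit(X, y)$residuals)
  const <- (n - p) * log(2 * pi) - ldetXtX

  # The residual variance is profiled out analytically: with V =
  # sigma_e2 * V0(lambda), lambda the variance ratios (sigma_a2/sigma_e2,
  # sigma_c2/sigma_e2), the restricted likelihood is maximised over
  # sigma_e2 in closed form (sigma_e2-hat = y'P0y / (n - p)), leaving a
  # 1-2 dimensional search over log ratios. This removes the scale
  # direction from the numerical optimisation entirely, which is what
  # limits how sharply the optimum can be located in double precision.
  nl <- 0L + use_a + use_c
  prof <- function(theta) {
    lam <- exp(theta)
    coefs <- 1
    lg <- 0
    k <- 1L
    if (use_a) { coefs <- c(coefs, 1 / lam[k]); lg <- lg + qa *
      log(lam[k]) + logdetA; k <- k + 1L }
    if (use_c) { coefs <- c(coefs, 1 / lam[k]); lg <- lg + qc *
      log(lam[k]) }
    Cmat <- assemble(sys, coefs)
    res <- tryCatch(chol_logdet_solve(chol0, Cmat, Wty),
                    error = function(e) NULL)
    if (is.null(res)) return(list(value = 1e10))
    quad0 <- sum((y - as.numeric(W %*% res$sol)) * y)
    if (!is.finite(quad0) || quad0 <= 0) return(list(value = 1e10))
    se2 <- quad0 / (n - p)
    list(value = const + (n - p) * (1 + log(se2)) + lg + res$ldet,
         se2 = se2)
  }
  neg2l <- function(theta) prof(theta)$value

  if (nl == 0L) {
    # fixed effects only: closed form
    se2_hat <- sum(stats::lm.fit(X, y)$residuals^2) / (n - p)
    fit <- list(par = numeric(0),
                objective = prof(numeric(0))$value,
                convergence = 0L, message = "closed form")
  } else {
    if (!is.null(opt$start)) {
      v0 <- rep(opt$start, length.out = nl + 1L)
      lam0 <- v0[seq_len(nl)] / v0[nl + 1L]
    } else {
      lam0 <- c(if (use_a) 0.3 / 0.65, if (use_c) 0.05 / 0.65)
    }
    lower <- rep(log(1e-9), nl)
    upper <- rep(log(1e9), nl)
    fit <- stats::nlminb(log(lam0), neg2l, lower = lower, upper = upper,
                         control = list(iter.max = opt$max_iter,
                                        eval.max = 4L * opt$max_iter,
                                        rel.tol = opt$rel_tol))
    pol <- newton_polish(neg2l, fit$par, fit$objective, lower, upper)
    if (opt$rel_tol < 1e-9 &&
        all(pol$par > lower + 0.5) && all(pol$par < upper - 0.5)) {
      deep <- tryCatch(
        stats::nlminb(pol$par, neg2l,
                      gradient = function(th) fd_gradient(neg2l, th),
                      lower = lower, upper = upper,
                      control = list(rel.tol = 1e-15, x.tol = 1e-14,
                                     iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(deep) && deep$objective <= pol$objective)
        pol <- list(par = deep$par, objective = deep$objective)
    }
    fit$par <- pol$par; fit$objective <- pol$objective
    se2_hat <- prof(fit$par)$se2
  }
  lam <- exp(fit$par)
  v <- c(lam * se2_hat, se2_hat)
  nv <- nl + 1L
  boundary <- v <= 1e-6 * vary

  # full (non-profiled) likelihood in the variances, for the observed
  # information at the optimum
  neg2l_full <- function(theta) {
    vv <- exp(theta)
    se2 <- vv[nv]
    k <- 1L
    coefs <- 1 / se2
    lg <- 0
    if (use_a) { coefs <- c(coefs, 1 / vv[k]); lg <- lg + qa *
      log(vv[k]) + logdetA; k <- k + 1L }
    if (use_c) { coefs <- c(coefs, 1 / vv[k]); lg <- lg + qc *
      log(vv[k]) }
    Cmat <- assemble(sys, coefs)
    res <- tryCatch(chol_logdet_solve(chol0, Cmat, Wty / se2),
                    error = function(e) NULL)
    if (is.null(res)) return(1e10)
    quad <- sum((y - as.numeric(W %*% res$sol)) * y) / se2
    const + n * log(se2) + lg + res$ldet + quad
  }
  k <- 1L
  sigma_a2 <- 0; sigma_c2 <- 0
  if (use_a) { sigma_a2 <- v[k]; k <- k + 1L }
  if (use_c) { sigma_c2 <- v[k]; k <- k + 1L }
  sigma_e2 <- v[length(v)]
  sigma_p2 <- sigma_a2 + sigma_c2 + sigma_e2
  h2 <- sigma_a2 / sigma_p2
  c2 <- sigma_c2 / sigma_p2

  ses <- c(h2 = NA_real_, c2 = NA_real_)
  vcov_v <- NULL
  near_zero <- v < 1e-5 * vary
  if (isTRUE(opt$se) && !any(near_zero)) {
    # observed information on the log scale (well conditioned), mapped to
    # the variance scale through d v / d theta = v
    H <- tryCatch(fd_hessian(neg2l_full, log(v)), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_v <- tryCatch(diag(v, nv) %*% (2 * solve(H)) %*% diag(v, nv),
                         error = function(e) NULL)
      if (!is.null(vcov_v) && all(diag(vcov_v) > 0)) {
        idx_a <- if (use_a) 1L else NA_integer_
        # gradients of a/(a+c+e) and c/(a+c+e) wrt fitted variances
        tot <- sum(c(sigma_a2, sigma_c2, sigma_e2))
        if (use_a) {
          g_h2 <- vapply(seq_len(nv), function(i)
            (as.numeric(i == idx_a) * tot - sigma_a2) / tot^2, 0)
          ses["h2"] <- sqrt(drop(t(g_h2) %*% vcov_v %*% g_h2))
        }
        if (use_c) {
          idx_c <- 1L + use_a
          g_c2 <- vapply(seq_len(nv), function(i)
            (as.numeric(i == idx_c) * tot - sigma_c2) / tot^2, 0)
          ses["c2"] <- sqrt(drop(t(g_c2) %*% vcov_v %*% g_c2))
        }
      }
    }
  }
  structure(list(sigma_a2 = sigma_a2, sigma_c2 = sigma_c2,
                 sigma_e2 = sigma_e2, sigma_p2 = sigma_p2,
                 h2 = h2, c2 = c2, se = ses,
                 loglik = -0.5 * fit$objective,
                 converged = fit$convergence == 0,
                 message = fit$message,
                 boundary = any(boundary),
                 n_used = n, random = random,
                 vcov_varcomp = vcov_v,
                 response = bundle$spec$response),
            class = "reml_uni")
}

#' @method print reml_uni
#' @export
print.reml_uni <- function(x, digits = 4, ...) {
  cat("Univariate REML animal model:", x$response, "\n")
  cat(sprintf("  sigma_a2 = %.*g  sigma_c2 = %.*g  sigma_e2 = %.*g  sigma_p2 = %.*g\n",
              digits, x$sigma_a2, digits, x$sigma_c2, digits, x$sigma_e2,
              digits, x$sigma_p2))
  cat(sprintf("  h2 = %.3f (SE %.3f)   c2 = %.3f (SE %.3f)\n",
              x$h2, x$se["h2"], x$c2, x$se["c2"]))
  cat(sprintf("  logLik = %.3f   n = %d   converged: %s%s\n", x$loglik,
              x$n_used, x$converged, if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' Heritability and common-environment ratio
#'
#' For a fitted \code{reml_uni} object, recomputes \eqn{h^2 =
#' \sigma_a^2/\sigma_p^2} and \eqn{c^2 = \sigma_c^2/\sigma_p^2} from the
#' stored components. For plain numbers, returns the ratio of the first
#' argument to the phenotypic variance.
#'
#' @param x a \code{reml_uni} fit, or a numeric variance component
#'   (\eqn{\sigma_a^2} or \eqn{\sigma_c^2}).
#' @param sigma_p2 phenotypic variance (required when \code{x} is numeric);
#'   must be positive.
#' @return For a fit: list with \code{h2} and \code{c2}. For numbers: the
#'   ratio.
#' @examples
#' heritability(8.90, 18.45)  # 0.48 at two decimals
#' @export
heritability <- function(x, sigma_p2 = NULL) {
  if (inherits(x, "reml_uni")) {
    if (x$sigma_p2 <= 0)
      stop("phenotypic variance must be positive", call. = FALSE)
    return(list(h2 = x$sigma_a2 / x$sigma_p2, c2 = x$sigma_c2 / x$sigma_p2))
  }
  if (is.null(sigma_p2) || any(sigma_p2 <= 0))
    stop("sigma_p2 must be supplied and positive", call. = FALSE)
  x / sigma_p2
}

# --- bivariate REML ----------------------------------------------------

#' Bivariate REML animal model
#'
#' Joint fit of two traits with additive-genetic covariance \eqn{A \otimes
#' G_0}, common-environment covariance \eqn{I \otimes C_0} and residual
#' covariance \eqn{I \otimes R_0}, where \eqn{G_0, C_0, R_0} are 2x2.
#' Each trait keeps its own fixed effects and record set; animals missing
#' one trait contribute through the other alone. The common-environment
#' term follows each bundle's spec, so it can be fitted on one trait only
#' (used when fitting it on both traits fails to converge, as for the
#' Ucrit-DGC pair). Variances are optimised on the log scale and
#' correlations through a tanh transform, which keeps every 2x2 block
#' positive semi-definite without post-hoc truncation.
#'
#' @param bundle1,bundle2 \code{\link{build_design}} bundles sharing one
#'   pedigree. At most one record per animal per trait.
#' @param fix_ra if 0, the additive covariance is constrained to zero (the
#'   reduced model of the genetic-correlation likelihood ratio test).
#' @param options as \code{\link{reml_univariate}}.
#' @return An object of class \code{reml_biv}: 2x2 matrices \code{G},
#'   \code{C}, \code{R}; correlations \code{rg}, \code{rc}, \code{re} and
#'   phenotypic correlation \code{rp} with delta-method SEs; per-trait
#'   \code{h2}, \code{c2}, \code{sigma_p2}; \code{loglik};
#'   \code{converged}; \code{boundary_cor} flag for correlations pinned
#'   near +/-1.
#' @export
reml_bivariate <- function(bundle1, bundle2, fix_ra = NULL,
                           options = list()) {
  stopifnot(inherits(bundle1, "design_bundle"),
            inherits(bundle2, "design_bundle"))
  if (!identical(bundle1$ped$animal, bundle2$ped$animal))
    stop("bundles must share one pedigree", call. = FALSE)
  if (anyDuplicated(bundle1$animal_idx) || anyDuplicated(bundle2$animal_idx))
    stop("at most one record per animal per trait", call. = FALSE)
  opt <- utils::modifyList(list(max_iter = 500L, rel_tol = 1e-8, se = TRUE,
                                start = NULL), options)
  use_c1 <- "common_env" %in% bundle1$spec$random
  use_c2 <- "common_env" %in% bundle2$spec$random
  ainv <- bundle1$ainv
  logdetA <- attr(ainv, "logdet")
  qa <- ncol(bundle1$Z1)
  # shared family level set
  fam_levels <- sort(unique(c(if (use_c1) bundle1$family,
                              if (use_c2) bundle2$family)))
  qc <- length(fam_levels)
  n1 <- bundle1$n_used; n2 <- bundle2$n_used
  p1 <- ncol(bundle1$X); p2 <- ncol(bundle2$X)
  # global columns: [X1][X2][a1][a2][c1?][c2?]
  col_a1 <- p1 + p2; col_a2 <- col_a1 + qa
  col_c1 <- col_a2 + qa
  col_c2 <- col_c1 + qa * 0 + if (use_c1) qc else 0L
  pdim <- p1 + p2 + 2L * qa + (use_c1 + use_c2) * qc
  row_block <- function(bundle, xoff, acol, ccol, use_c) {
    nn <- bundle$n_used
    Xs <- methods::as(Matrix::Matrix(bundle$X, sparse = TRUE),
                      "CsparseMatrix")
    parts <- list(
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(nn, xoff)),
      Xs,
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(nn, acol - xoff - ncol(Xs))),
      Matrix::sparseMatrix(i = seq_len(nn), j = bundle$animal_idx, x = 1,
                           dims = c(nn, qa)))
    W <- Reduce(methods::cbind2, parts)
    if (use_c) {
      Zc <- Matrix::sparseMatrix(i = seq_len(nn),
                                 j = match(bundle$family, fam_levels), x = 1,
                                 dims = c(nn, qc))
      pad <- ccol - ncol(W)
      if (pad > 0)
        W <- methods::cbind2(
          W, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                  x = numeric(0), dims = c(nn, pad)))
      W <- methods::cbind2(W, Zc)
    }
    if (ncol(W) < pdim)
      W <- methods::cbind2(
        W, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(nn, pdim - ncol(W))))
    methods::as(W, "CsparseMatrix")
  }
  W1 <- row_block(bundle1, 0L, col_a1, col_c1, use_c1)
  W2 <- row_block(bundle2, p1, col_a2, col_c2, use_c2)
  # partition rows by residual block structure
  dual_animals <- intersect(bundle1$animal_idx, bundle2$animal_idx)
  d1 <- match(dual_animals, bundle1$animal_idx)
  d2 <- match(dual_animals, bundle2$animal_idx)
  s1 <- setdiff(seq_len(n1), d1)
  s2 <- setdiff(seq_len(n2), d2)
  nd <- length(dual_animals)
  Wb1 <- W1[d1, , drop = FALSE]; Wb2 <- W2[d2, , drop = FALSE]
  Ws1 <- W1[s1, , drop = FALSE]; Ws2 <- W2[s2, , drop = FALSE]
  yb1 <- bundle1$y[d1]; yb2 <- bundle2$y[d2]
  ys1 <- bundle1$y[s1]; ys2 <- bundle2$y[s2]
  M11 <- Matrix::crossprod(Wb1); M22 <- Matrix::crossprod(Wb2)
  M12 <- Matrix::crossprod(Wb1, Wb2)
  M12s <- M12 + Matrix::t(M12)
  S1 <- Matrix::crossprod(Ws1); S2 <- Matrix::crossprod(Ws2)
  u11 <- as.numeric(Matrix::crossprod(Wb1, yb1))
  u12 <- as.numeric(Matrix::crossprod(Wb1, yb2))
  u21 <- as.numeric(Matrix::crossprod(Wb2, yb1))
  u22 <- as.numeric(Matrix::crossprod(Wb2, yb2))
  us1 <- as.numeric(Matrix::crossprod(Ws1, ys1))
  us2 <- as.numeric(Matrix::crossprod(Ws2, ys2))
  Ka11 <- embed_diag_block(ainv, col_a1, pdim)
  Ka22 <- embed_diag_block(ainv, col_a2, pdim)
  Ka12 <- embed_cross_block(ainv, col_a1, col_a2, pdim)
  comps <- list(M11, M22, M12s, S1, S2, Ka11, Ka22, Ka12)
  if (use_c1)
    comps <- c(comps, list(embed_diag_block(Matrix::Diagonal(qc), col_c1,
                                            pdim)))
  if (use_c2)
    comps <- c(comps, list(embed_diag_block(Matrix::Diagonal(qc), col_c2,
                                            pdim)))
  if (use_c1 && use_c2)
    comps <- c(comps, list(embed_cross_block(Matrix::Diagonal(qc), col_c1,
                                             col_c2, pdim)))
  sys <- component_system(comps)
  chol0 <- initial_cholesky(sys)
  ldetXtX <- logdet_dense(crossprod(bundle1$X)) +
    logdet_dense(crossprod(bundle2$X))
  const <- (n1 + n2 - p1 - p2) * log(2 * pi) - ldetXtX
  vary1 <- stats::var(stats::lm.fit(bundle1$X, bundle1$y)$residuals)
  vary2 <- stats::var(stats::lm.fit(bundle2$X, bundle2$y)$residuals)
  fix_ra0 <- !is.null(fix_ra) && fix_ra == 0
  rmax <- 0.999

  # parameter vector on the working scale:
  # log sa1, log sa2, [za], log sc1?, log sc2?, [zc?], log se1, log se2, ze
  par_names <- c("lsa1", "lsa2", if (!fix_ra0) "za",
                 if (use_c1) "lsc1", if (use_c2) "lsc2",
                 if (use_c1 && use_c2) "zc",
                 "lse1", "lse2", "ze")
  unpack <- function(theta) {
    names(theta) <- par_names
    g <- function(nm) unname(theta[nm])
    ra <- if (fix_ra0) 0 else tanh(g("za"))
    sa1 <- exp(g("lsa1")); sa2 <- exp(g("lsa2"))
    sc1 <- if (use_c1) exp(g("lsc1")) else 0
    sc2 <- if (use_c2) exp(g("lsc2")) else 0
    rc <- if (use_c1 && use_c2) tanh(g("zc")) else 0
    se1 <- exp(g("lse1")); se2 <- exp(g("lse2")); re <- tanh(g("ze"))
    list(sa1 = sa1, sa2 = sa2, ra = ra, sc1 = sc1, sc2 = sc2, rc = rc,
         se1 = se1, se2 = se2, re = re)
  }
  neg2l_par <- function(pp) {
    # residual inverse-block coefficients
    dete <- pp$se1 * pp$se2 * (1 - pp$re^2)
    v11 <- pp$se2 / dete; v22 <- pp$se1 / dete
    v12 <- -pp$re * sqrt(pp$se1 * pp$se2) / dete
    # additive G0 inverse
    deta <- pp$sa1 * pp$sa2 * (1 - pp$ra^2)
    g11 <- pp$sa2 / deta; g22 <- pp$sa1 / deta
    g12 <- -pp$ra * sqrt(pp$sa1 * pp$sa2) / deta
    coefs <- c(v11, v22, v12, 1 / pp$se1, 1 / pp$se2, g11, g22, g12)
    lgc <- 0
    if (use_c1 && use_c2) {
      detc <- pp$sc1 * pp$sc2 * (1 - pp$rc^2)
      coefs <- c(coefs, pp$sc2 / detc, pp$sc1 / detc,
                 -pp$rc * sqrt(pp$sc1 * pp$sc2) / detc)
      lgc <- qc * log(detc)
    } else if (use_c1) {
      coefs <- c(coefs, 1 / pp$sc1); lgc <- qc * log(pp$sc1)
    } else if (use_c2) {
      coefs <- c(coefs, 1 / pp$sc2); lgc <- qc * log(pp$sc2)
    }
    rhs <- v11 * u11 + v12 * (u12 + u21) + v22 * u22 +
      us1 / pp$se1 + us2 / pp$se2
    Cmat <- assemble(sys, coefs)
    res <- tryCatch(chol_logdet_solve(chol0, Cmat, rhs),
                    error = function(e) NULL)
    if (is.null(res)) return(1e10)
    r1 <- bundle1$y - as.numeric(W1 %*% res$sol)
    r2 <- bundle2$y - as.numeric(W2 %*% res$sol)
    quad <- v11 * sum(yb1 * r1[d1]) +
      v12 * (sum(yb1 * r2[d2]) + sum(yb2 * r1[d1])) +
      v22 * sum(yb2 * r2[d2]) +
      sum(ys1 * r1[s1]) / pp$se1 + sum(ys2 * r2[s2]) / pp$se2
    lR <- nd * log(dete) + length(s1) * log(pp$se1) +
      length(s2) * log(pp$se2)
    lG <- qa * log(deta) + 2 * logdetA + lgc
    const + lR + lG + res$ldet + quad
  }
  neg2l <- function(theta) neg2l_par(unpack(theta))

  # starting values from single-trait moments and the residual correlation
  r0 <- if (nd > 2) {
    r1 <- stats::lm.fit(bundle1$X[d1, , drop = FALSE], yb1)$residuals
    r2 <- stats::lm.fit(bundle2$X[d2, , drop = FALSE], yb2)$residuals
    max(min(stats::cor(r1, r2), 0.9), -0.9)
  } else 0
  start <- c(log(0.3 * vary1), log(0.3 * vary2),
             if (!fix_ra0) atanh(r0),
             if (use_c1) log(0.05 * vary1),
             if (use_c2) log(0.05 * vary2),
             if (use_c1 && use_c2) 0,
             log(0.65 * vary1), log(0.65 * vary2), atanh(r0 * 0.8))
  if (!is.null(opt$start)) start <- opt$start
  isz <- grepl("^z", par_names)
  lower <- ifelse(isz, -atanh(rmax),
                  log(1e-10 * min(vary1, vary2)))
  upper <- ifelse(isz, atanh(rmax),
                  log(1e5 * max(vary1, vary2)))
  fit <- stats::nlminb(start, neg2l, lower = lower, upper = upper,
                       control = list(iter.max = opt$max_iter,
                                      eval.max = 4L * opt$max_iter,
                                      rel.tol = opt$rel_tol))
  pp <- unpack(fit$par)
  G <- matrix(c(pp$sa1, pp$ra * sqrt(pp$sa1 * pp$sa2),
                pp$ra * sqrt(pp$sa1 * pp$sa2), pp$sa2), 2)
  Cm <- matrix(c(pp$sc1, pp$rc * sqrt(pp$sc1 * pp$sc2),
                 pp$rc * sqrt(pp$sc1 * pp$sc2), pp$sc2), 2)
  R <- matrix(c(pp$se1, pp$re * sqrt(pp$se1 * pp$se2),
                pp$re * sqrt(pp$se1 * pp$se2), pp$se2), 2)
  sp1 <- pp$sa1 + pp$sc1 + pp$se1
  sp2 <- pp$sa2 + pp$sc2 + pp$se2
  rp <- (G[1, 2] + (if (use_c1 && use_c2) Cm[1, 2] else 0) + R[1, 2]) /
    sqrt(sp1 * sp2)
  boundary_cor <- any(abs(c(pp$ra, pp$rc, pp$re)) > 0.995)

  ses <- c(rg = NA_real_, rc = NA_real_, re = NA_real_, rp = NA_real_,
           h2_1 = NA_real_, h2_2 = NA_real_)
  if (isTRUE(opt$se) && !boundary_cor) {
    summaries <- function(theta) {
      q <- unpack(theta)
      qp1 <- q$sa1 + q$sc1 + q$se1; qp2 <- q$sa2 + q$sc2 + q$se2
      c(rg = q$ra, rc = q$rc, re = q$re,
        rp = (q$ra * sqrt(q$sa1 * q$sa2) +
                (if (use_c1 && use_c2) q$rc * sqrt(q$sc1 * q$sc2) else 0) +
                q$re * sqrt(q$se1 * q$se2)) / sqrt(qp1 * qp2),
        h2_1 = q$sa1 / qp1, h2_2 = q$sa2 / qp2)
    }
    H <- tryCatch(fd_hessian(neg2l, fit$par), error = function(e) NULL)
    if (!is.null(H)) {
      Vt <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(Vt) && all(diag(Vt) > 0)) {
        J <- fd_jacobian(summaries, fit$par)
        Vout <- J %*% Vt %*% t(J)
        dv <- diag(Vout)
        ok <- dv > 0
        ses[ok] <- sqrt(dv[ok])
      }
    }
  }
  structure(list(G = G, C = Cm, R = R,
                 rg = pp$ra, rc = if (use_c1 && use_c2) pp$rc else NA_real_,
                 re = pp$re, rp = rp, se = ses,
                 h2 = c(pp$sa1 / sp1, pp$sa2 / sp2),
                 c2 = c(pp$sc1 / sp1, pp$sc2 / sp2),
                 sigma_p2 = c(sp1, sp2),
                 common_env = c(use_c1, use_c2),
                 loglik = -0.5 * fit$objective,
                 converged = fit$convergence == 0,
                 message = fit$message,
                 boundary_cor = boundary_cor,
                 n_used = c(n1, n2), n_dual = nd,
                 responses = c(bundle1$spec$response,
                               bundle2$spec$response)),
            class = "reml_biv")
}

#' @method print reml_biv
#' @export
print.reml_biv <- function(x, ...) {
  cat("Bivariate REML animal model:", paste(x$responses, collapse = " & "),
      "\n")
  cat(sprintf("  rg = %.3f (SE %.3f)  rc = %.3f  re = %.3f (SE %.3f)  rp = %.3f (SE %.3f)\n",
              x$rg, x$se["rg"], x$rc, x$re, x$se["re"], x$rp, x$se["rp"]))
  cat(sprintf("  h2: %.3f / %.3f   c2: %.3f / %.3f\n",
              x$h2[1], x$h2[2], x$c2[1], x$c2[2]))
  cat(sprintf("  logLik = %.3f   n = %d + %d (%d with both)  converged: %s%s\n",
              x$loglik, x$n_used[1], x$n_used[2], x$n_dual, x$converged,
              if (x$boundary_cor) "  [correlation at boundary]" else ""))
  invisible(x)
}

#' Phenotypic correlation from a bivariate fit
#'
#' \deqn{r_p = (G_{12} + C_{12} + R_{12}) / \sqrt{\sigma_{p1}^2
#'   \sigma_{p2}^2}} with the common-environment covariance included only
#' when the term was fitted on both traits.
#'
#' @param fit a \code{reml_biv} object.
#' @return Phenotypic correlation.
#' @export
phenotypic_correlation <- function(fit) {
  stopifnot(inherits(fit, "reml_biv"))
  sp <- fit$sigma_p2
  if (any(sp <= 0))
    stop("non-positive phenotypic variance", call. = FALSE)
  (fit$G[1, 2] + (if (all(fit$common_env)) fit$C[1, 2] else 0) +
      fit$R[1, 2]) / sqrt(sp[1] * sp[2])
}

#' Likelihood ratio test between nested REML fits
#'
#' \eqn{\chi^2 = \max(0, 2(\ell_{full} - \ell_{reduced}))} referred to a
#' one-degree-of-freedom chi-square upper tail. Tests of a variance
#' component sit on the boundary of the parameter space, making the
#' plain chi-square conservative; a 50:50 mixture of \eqn{\chi^2_0} and
#' \eqn{\chi^2_1} is available but off by default.
#'
#' @param full,reduced fitted objects with a \code{loglik} element, or
#'   restricted log-likelihoods directly.
#' @param df degrees of freedom (default 1).
#' @param boundary_mixture use the 50:50 mixture null distribution.
#' @return list with \code{chi2}, \code{df}, \code{p_value}.
#' @export
lrt <- function(full, reduced, df = 1L, boundary_mixture = FALSE) {
  ll <- function(x) if (is.numeric(x)) x else x$loglik
  lf <- ll(full); lr <- ll(reduced)
  if (lr > lf + 1e-6)
    warning("reduced model has higher log-likelihood than the full model; ",
            "check convergence/nesting", call. = FALSE)
  chi2 <- max(0, 2 * (lf - lr))
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  if (boundary_mixture)
    p <- if (chi2 == 0) 1 else 0.5 * p
  list(chi2 = chi2, df = as.integer(df), p_value = p)
}
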