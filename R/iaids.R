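#' Construct an inverse almost ideal demand system (IAIDS) parameter set
#'
#' An IAIDS describes how expenditure shares for a set of `n` goods respond to
#' exogenous quantities.  The structural share equation is
#' \deqn{w_i = \alpha_i + \sum_j \gamma_{ij} \ln q_j - \beta_i \ln Q,}
#' where \eqn{\ln Q} is a log-quantity index (translog or Stone).  The
#' parameters derive from a translog distance function and must satisfy the
#' utility-theoretic restriction set:
#' adding-up (\eqn{\sum_i \alpha_i = 1}, \eqn{\sum_i \beta_i = 0},
#' \eqn{\sum_i \gamma_{ij} = 0}), homogeneity (\eqn{\sum_j \gamma_{ij} = 0})
#' and symmetry (\eqn{\gamma_{ij} = \gamma_{ji}}).  With these restrictions the
#' free-parameter count is \eqn{(n-1) + (n-1) + n(n-1)/2} (12 when `n = 4`).
#'
#' `alpha0` and `beta0` are not identified by the share equations; they act as
#' normalisations of the distance function used in welfare measurement.
#'
#' @param alpha numeric n-vector of share intercepts, summing to 1.
#' @param beta numeric n-vector of scale coefficients, summing to 0.
#' @param gamma symmetric n x n matrix with zero row and column sums.
#' @param alpha0 translog constant (welfare normalisation), default 0.
#' @param beta0 positive scale constant (welfare normalisation), default 1.
#' @param vcov optional covariance matrix of the free parameter vector, as
#'   produced by [estimate_sur()].
#' @param labels optional character n-vector of good labels.
#' @param tol numeric tolerance for restriction checks.
#' @return An object of class `iaids_params`.
#' @seealso [predict_shares()], [estimate_sur()], [flexibilities()]
#' @export
iaids_params <- function(alpha, beta, gamma, alpha0 = 0, beta0 = 1,
                         vcov = NULL, labels = NULL, tol = 1e-8) {
  n <- length(alpha)
  gamma <- as.matrix(gamma)
  stopifnot(length(beta) == n, all(dim(gamma) == n), n >= 2)
  if (abs(sum(alpha) - 1) > tol)
    stop("adding-up violated: sum(alpha) must equal 1", call. = FALSE)
  if (abs(sum(beta)) > tol)
    stop("adding-up violated: sum(beta) must equal 0", call. = FALSE)
  if (max(abs(gamma - t(gamma))) > tol)
    stop("symmetry violated: gamma must be symmetric", call. = FALSE)
  if (max(abs(rowSums(gamma))) > tol)
    stop("homogeneity violated: gamma row sums must be 0", call. = FALSE)
  if (max(abs(colSums(gamma))) > tol)
    stop("adding-up violated: gamma column sums must be 0", call. = FALSE)
  if (beta0 <= 0) stop("beta0 must be positive", call. = FALSE)
  if (is.null(labels)) labels <- paste0("good", seq_len(n))
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  names(alpha) <- names(beta) <- labels
  dimnames(gamma) <- list(labels, labels)
  out <- structure(
    list(n = n, alpha0 = alpha0, alpha = alpha, beta0 = beta0, beta = beta,
         gamma = gamma, vcov = vcov, labels = labels,
         free_order = seq_len(n)),
    class = "iaids_params")
  out
}

#' @export
print.iaids_params <- function(x, ...) {
  cat("Inverse AIDS parameters:", x$n, "goods,",
      n_free_params(x$n), "free parameters\n")
  cat("alpha:", format(round(x$alpha, 4)), "\n")
  cat("beta: ", format(round(x$beta, 4)), "\n")
  cat("gamma:\n")
  print(round(x$gamma, 4))
  if (!is.null(x$vcov)) cat("(estimation covariance attached)\n")
  invisible(x)
}

# free parameters under adding-up + homogeneity + symmetry
n_free_params <- function(n) (n - 1L) + (n - 1L) + n * (n - 1L) / 2L

# pack free parameters: alpha[1..n-1], beta[1..n-1], upper triangle (incl.
# diagonal) of the leading (n-1) x (n-1) block of gamma
iaids_free <- function(p) {
  n <- p$n
  ut <- which(upper.tri(matrix(0, n - 1, n - 1), diag = TRUE))
  c(p$alpha[seq_len(n - 1)], p$beta[seq_len(n - 1)],
    p$gamma[seq_len(n - 1), seq_len(n - 1), drop = FALSE][ut])
}

# rebuild full params from the free vector; remaining entries follow from the
# restriction set (alpha_n from adding-up, gamma column n from homogeneity)
iaids_from_free <- function(theta, n, labels = NULL, alpha0 = 0, beta0 = 1,
                            vcov = NULL) {
  m <- n - 1L
  alpha <- c(theta[seq_len(m)], 1 - sum(theta[seq_len(m)]))
  beta <- c(theta[m + seq_len(m)], -sum(theta[m + seq_len(m)]))
  g <- matrix(0, m, m)
  g[upper.tri(g, diag = TRUE)] <- theta[2L * m + seq_len(n * m / 2L)]
  g <- g + t(g) - diag(diag(g), m)
  gamma <- matrix(0, n, n)
  gamma[seq_len(m), seq_len(m)] <- g
  gamma[seq_len(m), n] <- -rowSums(g)
  gamma[n, seq_len(m)] <- -rowSums(g)
  gamma[n, n] <- sum(g)
  iaids_params(alpha, beta, gamma, alpha0 = alpha0, beta0 = beta0,
               vcov = vcov, labels = labels)
}

#' Stone (linear-approximate) log-quantity index
#'
#' \eqn{\ln Q = \sum_j w_j \ln q_j}, the share-weighted mean of log
#' quantities.  This is the linear-approximate index used in LA-IAIDS
#' estimation.
#'
#' @param w shares: numeric vector, or matrix with one observation per row.
#' @param lnq log quantities, conforming with `w`.
#' @return numeric scalar (or vector, one per row).
#' @export
stone_index <- function(w, lnq) {
  if (is.matrix(w)) rowSums(w * lnq) else sum(w * lnq)
}

#' Translog log-quantity index
#'
#' \eqn{a(q) = \alpha_0 + \sum_i \alpha_i \ln q_i +
#' \tfrac12 \sum_i \sum_j \gamma_{ij} \ln q_i \ln q_j}, the exact quantity
#' aggregator of the IAIDS distance function.
#'
#' @param p an [iaids_params()] object.
#' @param lnq numeric vector (or one-row-per-observation matrix) of log
#'   quantities.
#' @return numeric scalar or vector.
#' @export
translog_index <- function(p, lnq) {
  if (is.matrix(lnq)) {
    p$alpha0 + drop(lnq %*% p$alpha) + 0.5 * rowSums((lnq %*% p$gamma) * lnq)
  } else {
    p$alpha0 + sum(p$alpha * lnq) + 0.5 * drop(t(lnq) %*% p$gamma %*% lnq)
  }
}

#' Predicted expenditure shares
#'
#' Evaluates the IAIDS share equations
#' \eqn{w_i = \alpha_i + \sum_j \gamma_{ij} \ln q_j - \beta_i \ln Q}.
#' When `lnQ` is omitted the exact translog index is used.  By the restriction
#' set the predicted shares sum to 1 identically.
#'
#' @param p an [iaids_params()] object.
#' @param lnq numeric vector (or matrix, observations in rows) of log
#'   quantities.
#' @param lnQ optional log-quantity index; defaults to [translog_index()].
#' @return shares, conforming with `lnq`.
#' @export
predict_shares <- function(p, lnq, lnQ = NULL) {
  if (is.null(lnQ)) lnQ <- translog_index(p, lnq)
  if (is.matrix(lnq)) {
    sweep(lnq %*% t(p$gamma), 2, p$alpha, "+") - outer(lnQ, p$beta)
  } else {
    drop(p$alpha + p$gamma %*% lnq - p$beta * lnQ)
  }
}

#' Shares consistent with the Stone index
#'
#' Solves the fixed point \eqn{w = \alpha + \Gamma \ln q - \beta (w'\ln q)}
#' so the emitted shares satisfy the LA-IAIDS share equations with the Stone
#' index computed from the shares themselves.  The solution is the linear
#' system \eqn{(I + \beta \ln q') w = \alpha + \Gamma \ln q}; adding-up
#' guarantees the solution sums to 1.
#'
#' @inheritParams predict_shares
#' @return shares, conforming with `lnq`.
#' @export
solve_shares <- function(p, lnq) {
  solve1 <- function(v) {
    drop(solve(diag(p$n) + outer(p$beta, v), p$alpha + p$gamma %*% v))
  }
  if (is.matrix(lnq)) t(apply(lnq, 1, solve1)) else solve1(lnq)
}

#' Estimate an IAIDS by iterated SUR/FGLS under full restrictions
#'
#' Fits the LA-IAIDS share system by seemingly unrelated regressions.  The
#' n-th share equation is dropped (adding-up makes the system covariance
#' singular); homogeneity is imposed by differencing log quantities against
#' the dropped good, and symmetry by sharing \eqn{\gamma_{ij}} across
#' equations.  Estimation iterates feasible GLS to the maximum-likelihood
#' fixed point; parameters of the dropped equation are recovered from
#' adding-up.  The Stone index is built from the observed shares.
#'
#' @param w T x n matrix of expenditure shares (rows sum to 1).
#' @param lnq T x n matrix of log quantities (centred; see
#'   [stage2_observations()]).
#' @param labels optional good labels; defaults to `colnames(w)`.
#' @param drop index of the equation to drop (default `n`); estimates are
#'   invariant to this choice on noise-free data.
#' @param tol convergence tolerance on the relative parameter change.
#' @param max_iter maximum FGLS iterations.
#' @return An [iaids_params()] object with the free-parameter covariance in
#'   `$vcov` and attributes `iterations` and `sigma` (residual covariance).
#' @export
estimate_sur <- function(w, lnq, labels = colnames(w), drop = ncol(w),
                         tol = 1e-8, max_iter = 100L) {
  w <- as.matrix(w); lnq <- as.matrix(lnq)
  n <- ncol(w); Tn <- nrow(w)
  stopifnot(ncol(lnq) == n, nrow(lnq) == Tn)
  K <- n_free_params(n)
  if (Tn < 3L * K)
    stop("need at least ", 3L * K, " observations to estimate ", K,
         " free parameters", call. = FALSE)
  if (any(apply(lnq, 2, stats::sd) < 1e-12))
    stop("degenerate (constant) log-quantity regressor", call. = FALSE)
  if (is.null(labels)) labels <- paste0("good", seq_len(n))

  ord <- c(setdiff(seq_len(n), drop), drop)   # dropped equation last
  wp <- w[, ord, drop = FALSE]
  qp <- lnq[, ord, drop = FALSE]
  lnQ <- stone_index(w, lnq)                  # permutation invariant
  m <- n - 1L
  x <- qp[, seq_len(m), drop = FALSE] - qp[, n]   # homogeneity imposed

  # design matrix for each retained equation; columns follow the free-vector
  # packing in iaids_free(): alpha_1..m, beta_1..m, gamma upper triangle.
  ut <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
  Xeq <- lapply(seq_len(m), function(i) {
    X <- matrix(0, Tn, K)
    X[, i] <- 1
    X[, m + i] <- -lnQ                         # share equation carries -beta*lnQ
    for (k in seq_len(nrow(ut))) {
      a <- ut[k, 1]; b <- ut[k, 2]
      if (a == i) X[, 2L * m + k] <- X[, 2L * m + k] + x[, b]
      if (b == i && a != i) X[, 2L * m + k] <- X[, 2L * m + k] + x[, a]
    }
    X
  })
  Y <- wp[, seq_len(m), drop = FALSE]

  sigma <- diag(m)
  theta <- NULL
  converged <- FALSE
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    S <- solve(sigma)
    A <- matrix(0, K, K); b <- numeric(K)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      A <- A + S[i, j] * crossprod(Xeq[[i]], Xeq[[j]])
      b <- b + S[i, j] * crossprod(Xeq[[i]], Y[, j])
    }
    theta_new <- drop(solve(A, b))
    resid <- Y - vapply(seq_len(m), function(i) drop(Xeq[[i]] %*% theta_new),
                        numeric(Tn))
    sigma_new <- crossprod(resid) / Tn
    scale <- mean(diag(sigma_new))
    if (scale < 1e-24) {            # perfect fit: noise-free data
      theta <- theta_new
      vc <- matrix(0, K, K)
      converged <- TRUE
      sigma <- sigma_new
      break
    }
    if (rcond(sigma_new) < 1e-12)
      stop("singular residual covariance; more (or more varied) data needed",
           call. = FALSE)
    delta <- if (is.null(theta)) Inf else
      max(abs(theta_new - theta) / pmax(abs(theta), 1e-8))
    trace <- c(trace, delta)
    theta <- theta_new
    sigma <- sigma_new
    if (delta < tol) {
      vc <- solve(A)
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("FGLS did not converge in ", max_iter,
         " iterations; relative changes: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
         call. = FALSE)

  p <- iaids_from_free(theta, n, labels = labels[ord], vcov = vc)
  # un-permute back to the input good order
  inv <- order(ord)
  out <- iaids_params(p$alpha[inv], p$beta[inv], p$gamma[inv, inv],
                      vcov = vc, labels = labels)
  out$free_order <- ord
  attr(out, "iterations") <- iter
  attr(out, "sigma") <- sigma
  out
}

#' Price flexibilities and elasticities at mean shares
#'
#' Uncompensated price flexibilities of the LA-IAIDS,
#' \deqn{f_{ij} = -\delta_{ij} + (\gamma_{ij} - \beta_i \bar w_j)/\bar w_i,}
#' evaluated at mean shares \eqn{\bar w}.  A flexibility is
#' \eqn{\partial \ln p_i / \partial \ln q_j}, the inverse-demand counterpart
#' of a price elasticity; the elasticity matrix reported alongside is the
#' inverse of the flexibility matrix.  When the parameter covariance is
#' available, inner-95th-percentile bounds for the own terms are computed by
#' the delta method.
#'
#' @param p an [iaids_params()] object.
#' @param wbar strictly positive mean shares (length n).
#' @param conf compute delta-method bounds for own terms (needs `p$vcov`).
#' @param level confidence level for the bounds.
#' @return A list of class `flexibility_table`: `flex` (matrix f), `elas`
#'   (matrix F^-1, NA with a warning if F is singular), and `own`, a
#'   data.frame of own flexibilities/elasticities with bounds.
#' @export
flexibilities <- function(p, wbar, conf = !is.null(p$vcov), level = 0.95) {
  stopifnot(length(wbar) == p$n, all(wbar > 0))
  f_at <- function(pp) {
    (pp$gamma - outer(pp$beta, wbar)) / wbar - diag(pp$n)
  }
  Fm <- f_at(p)
  dimnames(Fm) <- list(p$labels, p$labels)
  Em <- tryCatch(solve(Fm), error = function(e) {
    warning("flexibility matrix is singular; elasticities reported missing",
            call. = FALSE)
    matrix(NA_real_, p$n, p$n, dimnames = dimnames(Fm))
  })
  own <- data.frame(good = p$labels,
                    flexibility = diag(Fm),
                    elasticity = diag(Em),
                    row.names = NULL)
  if (conf) {
    if (is.null(p$vcov)) stop("no parameter covariance available", call. = FALSE)
    lo <- hi <- flo <- fhi <- numeric(p$n)
    for (i in seq_len(p$n)) {
      ci_f <- delta_method_ci(p, function(pp) f_at(pp)[i, i], level = level)
      flo[i] <- ci_f["lower"]; fhi[i] <- ci_f["upper"]
      ci_e <- delta_method_ci(p, function(pp) solve(f_at(pp))[i, i],
                              level = level)
      lo[i] <- ci_e["lower"]; hi[i] <- ci_e["upper"]
    }
    own$flex_lower <- flo; own$flex_upper <- fhi
    own$elas_lower <- lo; own$elas_upper <- hi
  }
  structure(list(flex = Fm, elas = Em, own = own, wbar = wbar),
            class = "flexibility_table")
}

#' @export
print.flexibility_table <- function(x, ...) {
  cat("Own-price flexibilities and elasticities (inverse demand):\n")
  print(x$own, digits = 4)
  invisible(x)
}

#' Delta-method confidence interval for a parameter functional
#'
#' Computes `point +/- z * se` where `se = sqrt(g' V g)`, `V` the covariance
#' of the free parameter vector and `g` the numerical gradient of the
#' statistic with respect to the free parameters (central differences).
#'
#' @param p an [iaids_params()] object with `$vcov` (from [estimate_sur()]).
#' @param statistic function taking an `iaids_params` object and returning a
#'   scalar.
#' @param level confidence level (default 0.95).
#' @return named numeric: `point`, `se`, `lower`, `upper`.
#' @export
delta_method_ci <- function(p, statistic, level = 0.95) {
  if (is.null(p$vcov)) stop("no parameter covariance in params", call. = FALSE)
  ord <- p$free_order
  inv <- order(ord)
  # free vector in the estimation (permuted) basis the vcov refers to
  p_perm <- iaids_params(p$alpha[ord], p$beta[ord], p$gamma[ord, ord],
                         alpha0 = p$alpha0, beta0 = p$beta0,
                         labels = p$labels[ord])
  theta <- iaids_free(p_perm)
  rebuild <- function(th) {
    pe <- iaids_from_free(th, p$n, labels = p$labels[ord],
                          alpha0 = p$alpha0, beta0 = p$beta0)
    iaids_params(pe$alpha[inv], pe$beta[inv], pe$gamma[inv, inv],
                 alpha0 = p$alpha0, beta0 = p$beta0, labels = p$labels)
  }
  point <- statistic(rebuild(theta))
  K <- length(theta)
  g <- numeric(K)
  for (k in seq_len(K)) {
    h <- 1e-6 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    g[k] <- (statistic(rebuild(tp)) - statistic(rebuild(tm))) / (2 * h)
  }
  se <- sqrt(max(0, drop(t(g) %*% p$vcov %*% g)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(point = point, se = se, lower = point - z * se, upper = point + z * se)
}
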