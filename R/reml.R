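#' Variance-structure model specification
#'
#' A linear mixed model for a covariate-residualized, standardized child
#' phenotype y with covariance
#' \deqn{V(\theta) = \sum_k \theta_k S_k,}
#' where each structure S_k is an aligned n x n symmetric matrix. The
#' offspring-only model uses S = (A_c, I); the extended parent-offspring
#' model uses S = (A_c, A_p, A_cp + A_cp', I), whose third term carries the
#' direct-nurture covariance: its diagonal contributes twice the
#' child-parent relatedness (2 x 0.5 = 1) times the covariance component,
#' so the phenotypic variance decomposes as
#' V_o + V_parent + V_cross + V_e.
#'
#' @param structures Named list of n x n matrices, in the order they are
#'   parameterized; an identity residual term named \code{V_e} is appended
#'   if absent.
#' @param nonneg Logical per structure: constrain the component to be
#'   nonnegative (default: TRUE for every term except names containing
#'   "cross" or starting with "V_o" + "m"/"f" covariance naming; pass
#'   explicitly for clarity).
#' @return Object of class \code{model_spec}.
#' @export
model_spec <- function(structures, nonneg = NULL) {
  stopifnot(is.list(structures), length(structures) >= 1,
            !is.null(names(structures)))
  n <- nrow(structures[[1]])
  for (nm in names(structures)) {
    S <- structures[[nm]]
    if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
      stop("structure '", nm, "' is not an aligned ", n, " x ", n, " matrix")
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop("structure '", nm, "' is not symmetric (symmetrize cross terms)")
  }
  if (!"V_e" %in% names(structures))
    structures$V_e <- diag(n)
  if (is.null(nonneg))
    nonneg <- !grepl("cross|v_om|v_of", names(structures),
                     ignore.case = TRUE)
  nonneg <- stats::setNames(rep_len(nonneg, length(structures)),
                            names(structures))
  structure(list(structures = structures, nonneg = nonneg, n = n),
            class = "model_spec")
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates, up to an additive constant,
#' \deqn{\ell_R(\theta) = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| +
#'   y'Py\right],}
#' with X the intercept column (covariates are removed beforehand) and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}} the REML projection.
#'
#' @param y Numeric phenotype vector (residualized, standardized).
#' @param spec A [model_spec()].
#' @param params Named or positional numeric vector of components theta.
#' @return The restricted log-likelihood (scalar). A non-positive-definite
#'   V signals an error of class \code{triogreml_nonpd}.
#' @export
restricted_loglik <- function(y, spec, params) {
  stopifnot(inherits(spec, "model_spec"), length(y) == spec$n,
            length(params) == length(spec$structures))
  V <- build_V(spec, params)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop(structure(class = c("triogreml_nonpd", "error", "condition"),
                   list(message = "V(theta) is not positive definite",
                        call = sys.call(-1))))
  logdet_V <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, spec$n)))
  s <- sum(Vi_1)                       # X'V^-1 X for X = 1
  yPy <- sum(y * Vi_y) - sum(y * Vi_1)^2 / s
  -0.5 * (logdet_V + log(s) + yPy)
}

build_V <- function(spec, params) {
  V <- matrix(0, spec$n, spec$n)
  for (k in seq_along(spec$structures))
    V <- V + params[k] * spec$structures[[k]]
  V
}

#' Fit a variance-component model by average-information REML
#'
#' Average-information (AI) REML with an expectation-maximization first
#' step and EM fallback whenever an AI step fails (non-positive-definite
#' V, singular AI matrix, or a decrease in the restricted likelihood after
#' step halving). Nonnegative components are floored at zero when a step
#' goes negative (the covariance term is exempt and free in sign);
#' convergence is declared when the relative change in restricted
#' log-likelihood falls below \code{tol}, with a maximum of
#' \code{max_iter} iterations (flagged if exhausted). Standard errors come
#' from the inverse AI matrix at the optimum. With y standardized to unit
#' variance, the estimates are directly proportions of phenotypic
#' variance.
#'
#' @param y Residualized, standardized phenotype vector.
#' @param spec A [model_spec()].
#' @param start Optional start values; default splits the phenotypic
#'   variance equally over the nonnegative terms, covariance terms at 0.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @param verbose Print per-iteration log-likelihoods.
#' @return Object of class \code{vc_fit}: list with \code{estimates}
#'   (named vector), \code{se}, \code{cov} (parameter covariance from the
#'   inverse AI matrix, NA if singular), \code{logL}, \code{n},
#'   \code{iterations}, \code{converged}, \code{boundary} (logical per
#'   parameter).
#' @export
reml_fit <- function(y, spec, start = NULL, tol = 1e-8, max_iter = 100L,
                     verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n
  k <- length(spec$structures)
  if (n < k + 10) stop("need n >= number of parameters + 10")
  vp <- stats::var(y)
  nonneg <- spec$nonneg
  floor_val <- 0
  e_floor <- 1e-6 * vp                  # keep V_e strictly positive
  if (is.null(start)) {
    start <- ifelse(nonneg, vp / sum(nonneg), 0)
    names(start) <- names(spec$structures)
  }
  theta <- start

  S <- spec$structures
  project <- function(th) {
    th[nonneg] <- pmax(th[nonneg], floor_val)
    if (nonneg["V_e"]) th["V_e"] <- max(th["V_e"], e_floor)
    th
  }
  theta <- project(theta)

  # returns P-derived quantities at theta, or NULL if V not PD
  decompose <- function(th) {
    V <- build_V(spec, th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    u <- rowSums(Vi)                    # Vi %*% 1
    s <- sum(u)
    P <- Vi - tcrossprod(u) / s
    Py <- drop(P %*% y)
    yPy <- sum(y * Py)
    logL <- -0.5 * (2 * sum(log(diag(ch))) + log(s) + yPy)
    list(P = P, Py = Py, logL = logL)
  }

  dec <- decompose(theta)
  if (is.null(dec)) stop("start values give a non-positive-definite V")
  logL <- dec$logL
  converged <- FALSE
  iter <- 0L
  AI <- NULL

  while (iter < max_iter) {
    iter <- iter + 1L
    P <- dec$P; Py <- dec$Py
    q <- vapply(S, function(Sk) drop(Sk %*% Py), numeric(n))   # n x k
    tPS <- vapply(S, function(Sk) sum(P * Sk), numeric(1))     # tr(P S_k)
    ySy <- colSums(q * Py)                                     # y'P S_k P y
    grad <- -0.5 * (tPS - ySy)
    Pq <- P %*% q
    AI <- 0.5 * crossprod(q, Pq)

    step_ok <- FALSE
    # active set: components pinned at the floor whose gradient points
    # further negative stay fixed; the Newton system is solved over the rest
    at_floor <- nonneg & theta <= floor_val + 1e-12
    if (nonneg["V_e"]) at_floor["V_e"] <- theta["V_e"] <= e_floor * 1.01
    active <- at_floor & grad < 0
    free <- which(!active)
    d_ai <- NULL
    if (length(free) > 0) {
      d_free <- tryCatch(solve(AI[free, free, drop = FALSE], grad[free]),
                         error = function(e) NULL)
      if (!is.null(d_free)) {
        d_ai <- numeric(k)
        d_ai[free] <- d_free
      }
    } else {
      # every parameter satisfies the boundary KKT condition
      converged <- TRUE
      break
    }
    use_em <- iter == 1L || is.null(d_ai)
    if (!use_em) {
      # AI step with halving until logL does not decrease and V stays PD
      for (h in 0:12) {
        cand <- project(theta + d_ai / 2^h)
        dec_new <- decompose(cand)
        if (!is.null(dec_new) && dec_new$logL >= logL - 1e-10) {
          step_ok <- TRUE; break
        }
      }
    }
    if (!step_ok) {
      # EM update: theta_k <- theta_k + theta_k^2/n (y'P S_k P y - tr(P S_k))
      cand <- theta + theta^2 / n * (ySy - tPS)
      # free (covariance) terms at 0 have zero EM gain; nudge along gradient
      free0 <- !nonneg & abs(theta) < 1e-12
      cand[free0] <- theta[free0] + grad[free0] / n
      dec_new <- NULL
      for (h in 0:12) {
        cand_h <- project(theta + (cand - theta) / 2^h)
        dec_new <- decompose(cand_h)
        if (!is.null(dec_new)) { cand <- cand_h; break }
      }
      if (is.null(dec_new)) {
        warning("REML: no positive-definite step found; stopping")
        break
      }
    }
    delta <- dec_new$logL - logL
    theta <- cand
    dec <- dec_new
    logL <- dec_new$logL
    if (verbose)
      message(sprintf("it %2d logL %.6f  %s", iter, logL,
                      paste(sprintf("%.4f", theta), collapse = " ")))
    if (abs(delta) / (abs(logL) + 1) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  # refresh AI at the optimum for standard errors
  P <- dec$P; Py <- dec$Py
  q <- vapply(S, function(Sk) drop(Sk %*% Py), numeric(n))
  AI <- 0.5 * crossprod(q, P %*% q)
  cov_theta <- tryCatch(solve(AI), error = function(e) NULL)
  se <- if (is.null(cov_theta)) rep(NA_real_, k) else sqrt(pmax(diag(cov_theta), 0))
  boundary <- nonneg & theta <= floor_val + 1e-10
  boundary["V_e"] <- nonneg["V_e"] & theta["V_e"] <= e_floor + 1e-12

  structure(list(estimates = theta,
                 se = stats::setNames(se, names(theta)),
                 cov = cov_theta, logL = logL, n = n,
                 iterations = iter, converged = converged,
                 boundary = boundary),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("<vc_fit> n = %d, logL = %.4f, %d iteration(s)%s\n",
              x$n, x$logL, x$iterations,
              if (x$converged) "" else " [NOT CONVERGED]"))
  tab <- data.frame(estimate = round(x$estimates, 4),
                    se = round(x$se, 4),
                    boundary = x$boundary)
  print(tab)
  invisible(x)
}

#' Likelihood-ratio test between nested REML fits
#'
#' @param full,reduced \code{vc_fit} objects (or anything with
#'   \code{$logL}), reduced nested in full.
#' @param df Degrees of freedom = difference in free parameters (2 for the
#'   parent + covariance terms).
#' @return List with \code{statistic} (2 x logL difference, floored at 0)
#'   and \code{p} from the chi-square upper tail. The boundary-constrained
#'   mixture correction is not applied; with variance components on the
#'   boundary the plain chi-square p-value is conservative.
#' @export
lrt <- function(full, reduced, df) {
  stat <- 2 * (full$logL - reduced$logL)
  if (stat < -1e-6)
    stop("full-model logL below reduced-model logL (",
         signif(stat / 2, 6), "); optimizer fault")
  stat <- max(stat, 0)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Combined direct plus indirect genetic variance G
#'
#' G is defined as the sum of the direct, parental-nurture, and covariance
#' components, \eqn{G = V_o + V_{parent} + V_{cross}}; its standard error
#' comes from the delta method (sum of the component variances plus twice
#' every pairwise covariance).
#'
#' @param v_o,v_parent,v_cross Component point estimates, or a
#'   \code{vc_fit} as the single first argument.
#' @param cov Optional 3x3 parameter covariance matrix (ordered V_o,
#'   V_parent, V_cross) for the delta-method SE.
#' @return List with \code{g} and \code{g_se} (NA when no covariance is
#'   available).
#' @export
combined_g <- function(v_o, v_parent = NULL, v_cross = NULL, cov = NULL) {
  if (inherits(v_o, "vc_fit")) {
    fit <- v_o
    comp <- setdiff(names(fit$estimates), "V_e")
    est <- fit$estimates[comp]
    cv <- if (!is.null(fit$cov)) {
      ci <- match(comp, names(fit$estimates))
      fit$cov[ci, ci, drop = FALSE]
    }
    return(list(g = sum(est),
                g_se = if (is.null(cv)) NA_real_ else sqrt(max(sum(cv), 0))))
  }
  g <- v_o + v_parent + v_cross
  g_se <- if (is.null(cov)) NA_real_ else sqrt(max(sum(cov), 0))
  list(g = g, g_se = g_se)
}
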