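#' Exact conditional log-likelihood of one stratum
#'
#' For a stratum with d cases among n subjects and linear predictors
#' eta, the conditional likelihood is exp(sum of case etas) divided by the
#' sum of exp(sum of etas) over all subsets of size d — the likelihood of a
#' matched set, free of the stratum intercept. The denominator (an
#' elementary symmetric function) is evaluated by the stable recursion
#' f(j, r) = f(j-1, r) + f(j-1, r-1) exp(eta_j), never by subset
#' enumeration; the gradient with respect to eta comes from the
#' differentiated recursion.
#'
#' A stratum with no cases or no controls is non-informative: it
#' contributes log-likelihood 0 and a zero gradient, and is flagged.
#'
#' @param eta Numeric vector of per-subject linear predictors.
#' @param case Logical/0-1 vector of case indicators, same length.
#' @return list with `loglik`, `gradient` (d loglik / d eta) and
#'   `informative` (logical).
#' @export
stratum_condloglik <- function(eta, case) {
  stopifnot(length(eta) == length(case))
  y <- as.integer(as.logical(case))
  n <- length(eta)
  d <- sum(y)
  if (d == 0L || d == n)
    return(list(loglik = 0, gradient = numeric(n), informative = FALSE))
  st <- cond_stats_cpp(eta, diag(n), y, 1L, n)
  list(loglik = st$loglik, gradient = as.numeric(st$score), informative = TRUE)
}

breslow_stats <- function(eta, X, y, starts, ends) {
  p <- ncol(X)
  ll <- 0; score <- numeric(p); info <- matrix(0, p, p); informative <- 0L
  for (s in seq_along(starts)) {
    ix <- starts[s]:ends[s]
    d <- sum(y[ix])
    if (d == 0L || d == length(ix)) next
    informative <- informative + 1L
    e <- eta[ix] - max(eta[ix])
    w <- exp(e)
    sw <- sum(w)
    xb <- colSums(X[ix, , drop = FALSE] * w) / sw
    ll <- ll + sum(e[y[ix] == 1]) - d * log(sw)
    score <- score + colSums(X[ix, , drop = FALSE][y[ix] == 1, , drop = FALSE]) - d * xb
    xc <- sweep(X[ix, , drop = FALSE], 2, xb)
    info <- info + d * crossprod(xc * sqrt(w / sw), xc * sqrt(w / sw))
    ll  # keep ll numeric scalar
  }
  list(loglik = ll, score = score, info = info, n_informative = informative)
}

#' Fit stratified conditional logistic regression
#'
#' Maximizes the exact conditional likelihood (default) by Newton-Raphson
#' with step halving. Convergence requires a relative log-likelihood change
#' below `ll_tol` and a maximum absolute score below `score_tol`; the
#' covariance is the inverse observed information at the optimum.
#' Non-informative strata (all cases or all controls) are dropped and
#' counted. Monotone likelihood (separation) is detected by diverging
#' coefficients and reported — never returned as a silent result.
#'
#' @param X Numeric design matrix (no intercept: it is conditioned out).
#' @param y Case indicators (logical or 0/1).
#' @param strata Stratum identifiers (the matching factors, e.g. the
#'   age-group x sex x region cross-classification).
#' @param likelihood "exact" (elementary-symmetric-function recursion) or
#'   "breslow" (the standard approximation; adequate when cases are a small
#'   fraction of each stratum).
#' @param max_iter,ll_tol,score_tol Newton-Raphson controls.
#' @return An `rfjem_clogit` object: list with `coefficients`, `vcov`,
#'   `loglik`, `null_loglik`, `n_informative_strata`, `n_dropped_strata`,
#'   `converged`, `monotone`, `iterations`, `likelihood`.
#' @export
fit_condlogit <- function(X, y, strata, likelihood = c("exact", "breslow"),
                          max_iter = 50L, ll_tol = 1e-8, score_tol = 1e-6) {
  likelihood <- match.arg(likelihood)
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(as.logical(y))
  stopifnot(nrow(X) == length(y), length(strata) == length(y))

  ord <- order(as.character(strata))
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  s <- as.character(strata)[ord]
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  d_k <- vapply(seq_along(starts), function(i) sum(y[starts[i]:ends[i]]), integer(1))
  n_k <- runs$lengths
  informative <- d_k > 0L & d_k < n_k
  n_dropped <- sum(!informative)
  if (!any(informative))
    stop("no informative strata: every stratum is all-case or all-control")
  null_ll <- sum(-lchoose(n_k[informative], d_k[informative]))

  stats_at <- function(beta) {
    eta <- as.numeric(X %*% beta)
    if (likelihood == "exact")
      cond_stats_cpp(eta, X, y, starts, ends)
    else
      breslow_stats(eta, X, y, starts, ends)
  }

  p <- ncol(X)
  beta <- numeric(p)
  if (p == 0L) {
    return(structure(list(coefficients = numeric(0),
                          vcov = matrix(0, 0, 0), loglik = null_ll,
                          null_loglik = null_ll,
                          n_informative_strata = sum(informative),
                          n_dropped_strata = n_dropped, converged = TRUE,
                          monotone = FALSE, iterations = 0L,
                          likelihood = likelihood),
                     class = "rfjem_clogit"))
  }
  qrX <- qr(X[rep(informative, runs$lengths), , drop = FALSE])
  if (qrX$rank < p)
    stop("design matrix rank-deficient on informative strata (",
         qrX$rank, " < ", p, ")")

  st <- stats_at(beta)
  ll <- st$loglik
  converged <- FALSE; monotone <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(st$info, st$score), error = function(e) NULL)
    if (is.null(delta)) { monotone <- TRUE; break }
    step <- 1
    repeat {
      cand <- beta + step * delta
      st_new <- stats_at(cand)
      if (is.finite(st_new$loglik) && st_new$loglik >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-8) break
    }
    rel_change <- abs(st_new$loglik - ll) / (abs(ll) + 1e-12)
    beta <- beta + step * delta
    ll <- st_new$loglik
    st <- st_new
    if (max(abs(beta)) > 15) { monotone <- TRUE; break }
    if (rel_change < ll_tol && max(abs(st$score)) < score_tol) {
      converged <- TRUE
      break
    }
  }
  vc <- tryCatch(solve(st$info), error = function(e) matrix(NA_real_, p, p))
  if (anyNA(vc)) converged <- FALSE
  names(beta) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vc, loglik = ll,
                 null_loglik = null_ll,
                 n_informative_strata = sum(informative),
                 n_dropped_strata = n_dropped, converged = converged,
                 monotone = monotone, iterations = iter,
                 likelihood = likelihood),
            class = "rfjem_clogit")
}

#' @export
print.rfjem_clogit <- function(x, ...) {
  cat("Stratified conditional logistic regression (", x$likelihood,
      " likelihood)\n", sep = "")
  cat(sprintf("  %d informative strata (%d dropped); loglik %.4f; %s in %d iter\n",
              x$n_informative_strata, x$n_dropped_strata, x$loglik,
              if (x$converged) "converged" else
                if (x$monotone) "NOT converged (monotone likelihood/separation)"
                else "NOT converged", x$iterations))
  if (length(x$coefficients)) print(odds_ratios_table(x))
  invisible(x)
}

#' @export
coef.rfjem_clogit <- function(object, ...) object$coefficients

#' @export
vcov.rfjem_clogit <- function(object, ...) object$vcov

odds_ratios_table <- function(fit, level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  data.frame(term = names(b), beta = b, se = se, OR = exp(b),
             CI_low = exp(b - z * se), CI_high = exp(b + z * se),
             p = 2 * stats::pnorm(-abs(b / se)), row.names = NULL)
}

#' Odds ratios with Wald confidence intervals
#'
#' OR = exp(beta); the default 95% interval is exp(beta +/- 1.96 se).
#'
#' @param fit A converged `rfjem_clogit`.
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `term,beta,se,OR,CI_low,CI_high,p`.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rfjem_clogit"))
  if (!fit$converged)
    stop("refusing to report odds ratios from a non-converged fit",
         if (isTRUE(fit$monotone)) " (monotone likelihood: separation suspected)"
         else "")
  odds_ratios_table(fit, level)
}

#' Wald trend test over ordered exposure categories
#'
#' Replaces the category indicators by a single ordinal score (0 =
#' unexposed through 4 = highest) and tests its coefficient. If the score
#' does not vary within any informative stratum the coefficient is not
#' estimable; by symmetry the test is then reported as beta 0, p = 1.
#'
#' @param score Ordinal exposure score per subject (e.g.
#'   `as.numeric(categories) - 1`).
#' @param y Case indicators.
#' @param strata Stratum identifiers.
#' @param adjust Optional matrix of adjustment covariates (e.g. education
#'   indicators).
#' @param likelihood Passed to [fit_condlogit()].
#' @return list with `beta`, `se`, `p`, `fit`.
#' @export
trend_test <- function(score, y, strata, adjust = NULL,
                       likelihood = c("exact", "breslow")) {
  likelihood <- match.arg(likelihood)
  varies <- any(stats::ave(score, as.character(strata),
                           FUN = function(v) stats::var(v)) > 0, na.rm = TRUE)
  if (!varies)
    return(list(beta = 0, se = NA_real_, p = 1, fit = NULL))
  X <- cbind(trend = score, adjust)
  fit <- fit_condlogit(X, y, strata, likelihood = likelihood)
  if (!fit$converged)
    return(list(beta = unname(fit$coefficients["trend"]), se = NA_real_,
                p = NA_real_, fit = fit))
  b <- fit$coefficients["trend"]
  se <- sqrt(fit$vcov["trend", "trend"])
  list(beta = unname(b), se = se, p = unname(2 * stats::pnorm(-abs(b / se))),
       fit = fit)
}
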