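# Significance of regulatory z-scores.
#
# Two routes, always computed side by side:
#   single  — upper tail of the standard normal at each z-score. Simple but
#             conservative when the score distribution is skewed or bimodal.
#   mixture — a two-component Gaussian mixture is fitted to the z-scores by
#             EM; p-values are the upper tail of the background component
#             (the one with the smaller mean). This separates non-target
#             genes (low scores) from genuine targets (high scores) and
#             recovers the sensitivity the single-normal route loses.
# Both p-value sets are BH-adjusted; target calls use whichever route the
# caller selects.

#' Fit a two-component Gaussian mixture by EM
#'
#' Maximizes the mixture log-likelihood
#' \deqn{\ell(\Theta \mid y) = \sum_i \log\left(\sum_{k=1}^2 w_k\,
#'   N(y_i \mid \mu_k, \sigma_k)\right)}
#' by expectation-maximization: the E-step computes posterior membership
#' probabilities \eqn{\hat z_{ik} = w_k N(y_i|\mu_k,\sigma_k) / \sum_h w_h
#' N(y_i|\mu_h,\sigma_h)}, and the M-step re-estimates
#' \eqn{\hat w_k = \sum_i \hat z_{ik}/n}, \eqn{\hat\mu_k = \sum_i \hat
#' z_{ik} y_i / \sum_i \hat z_{ik}} and \eqn{\hat\sigma_k^2 = \sum_i \hat
#' z_{ik}(y_i-\hat\mu_k)^2 / \sum_i \hat z_{ik}}.
#'
#' The default initialization splits the data at the 90th percentile
#' (background below, candidate targets above), which is deterministic;
#' `restarts - 1` additional runs perturb that initialization at random
#' under `seed`, and the best final log-likelihood wins. Components are
#' relabeled after fitting so component 1 has the smaller mean. A variance
#' floor guards against the classic likelihood singularity; if every
#' restart collapses onto a degenerate component the fit falls back to a
#' single Gaussian and is flagged not converged.
#'
#' @param z Numeric vector of at least 10 finite values (the z-scores).
#' @param tol Convergence tolerance on the change in log-likelihood.
#' @param max_iter Maximum EM iterations per restart.
#' @param restarts Number of initializations (1 = deterministic quantile
#'   split only).
#' @param seed Integer seed for the randomized restarts.
#' @param var_floor Lower bound on component variances.
#' @return An object of class `"gmm2"`: a list with elements `w`, `mu`,
#'   `sigma` (each length 2, component 1 = smaller mean), `loglik`,
#'   `loglik_trace` (nondecreasing within the winning run), `n_iter`,
#'   `converged`, `degenerate`, `n` and `z` (the data). Use [tidy()] /
#'   [glance()] for tabular summaries and `ggplot2::autoplot()` for the
#'   density overlay.
#' @examples
#' set.seed(42)
#' z <- c(rnorm(900), rnorm(100, mean = 4))
#' fit <- fit_gmm2(z, seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
fit_gmm2 <- function(z, tol = 1e-8, max_iter = 500L, restarts = 5L, seed = 1L,
                     var_floor = 1e-4) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 10L) abort("need at least 10 finite z-scores to fit the mixture")

  inits <- withr::with_seed(seed, {
    lapply(seq_len(max(1L, restarts)), function(r) gmm2_init(z, randomized = r > 1L))
  })
  fits <- lapply(inits, function(init) {
    gmm2_em(z, init, tol = tol, max_iter = max_iter, var_floor = var_floor)
  })
  ok <- !vapply(fits, `[[`, logical(1), "collapsed")
  if (!any(ok)) {
    fit <- list(
      w = c(1, 0), mu = rep(mean(z), 2), sigma = rep(sd(z), 2),
      loglik = sum(dnorm(z, mean(z), sd(z), log = TRUE)),
      loglik_trace = numeric(), n_iter = 0L, converged = FALSE, degenerate = TRUE
    )
  } else {
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    lls[!ok] <- -Inf
    fit <- fits[[which.max(lls)]]
    fit$degenerate <- FALSE
  }
  # component 1 = background (smaller mean)
  o <- order(fit$mu)
  fit$w <- fit$w[o]
  fit$mu <- fit$mu[o]
  fit$sigma <- fit$sigma[o]
  fit$collapsed <- NULL
  fit$n <- n
  fit$z <- z
  structure(fit, class = "gmm2")
}

gmm2_init <- function(z, randomized = FALSE) {
  q90 <- stats::quantile(z, 0.9, names = FALSE)
  lo <- z[z <= q90]
  hi <- z[z > q90]
  if (length(hi) < 2L) {
    hi <- sort(z, decreasing = TRUE)[1:2]
    lo <- z
  }
  init <- list(
    w = c(length(lo), length(hi)) / (length(lo) + length(hi)),
    mu = c(mean(lo), mean(hi)),
    sigma = pmax(c(sd(lo), sd(hi)), 0.05)
  )
  if (randomized) {
    init$mu <- init$mu + rnorm(2, sd = 0.5 * sd(z))
    init$sigma <- init$sigma * exp(rnorm(2, sd = 0.3))
    u <- runif(1, 0.05, 0.5)
    init$w <- c(1 - u, u)
  }
  init
}

gmm2_em <- function(z, init, tol, max_iter, var_floor) {
  n <- length(z)
  w <- init$w
  mu <- init$mu
  sigma <- init$sigma
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step in log space for numerical stability
    lp <- cbind(
      log(w[1]) + dnorm(z, mu[1], sigma[1], log = TRUE),
      log(w[2]) + dnorm(z, mu[2], sigma[2], log = TRUE)
    )
    m <- pmax(lp[, 1], lp[, 2])
    lse <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol) {
      converged <- TRUE
      break
    }
    prev <- ll
    post <- exp(lp - lse)
    nk <- colSums(post)
    if (any(nk < 1e-8)) {
      return(list(collapsed = TRUE, loglik = -Inf))
    }
    # M-step
    w <- nk / n
    mu <- colSums(post * z) / nk
    v <- colSums(post * (outer(z, mu, `-`))^2) / nk
    v <- pmax(v, var_floor)
    sigma <- sqrt(v)
    if (any(w < 1e-6)) {
      return(list(collapsed = TRUE, loglik = -Inf))
    }
  }
  list(
    w = w, mu = mu, sigma = sigma,
    loglik = trace[length(trace)], loglik_trace = trace,
    n_iter = iter, converged = converged, collapsed = FALSE
  )
}

#' @export
print.gmm2 <- function(x, ...) {
  cat("Two-component Gaussian mixture (EM)\n")
  cat(sprintf("  n = %d, log-likelihood = %.4f, iterations = %d, converged: %s%s\n",
              x$n, x$loglik, x$n_iter, x$converged,
              if (isTRUE(x$degenerate)) " (degenerate single-component fallback)" else ""))
  cat(sprintf("  background: w = %.3f, mu = %.3f, sigma = %.3f\n", x$w[1], x$mu[1], x$sigma[1]))
  cat(sprintf("  target:     w = %.3f, mu = %.3f, sigma = %.3f\n", x$w[2], x$mu[2], x$sigma[2]))
  invisible(x)
}

#' Tidy a two-component mixture fit
#'
#' @param x A `gmm2` fit from [fit_gmm2()].
#' @param ... Unused.
#' @return One row per component: `component` (`"background"`/`"target"`),
#'   `weight`, `mean`, `sd`.
#' @export
tidy.gmm2 <- function(x, ...) {
  tibble(
    component = c("background", "target"),
    weight = x$w,
    mean = x$mu,
    sd = x$sigma
  )
}

#' One-row summary of a two-component mixture fit
#'
#' @param x A `gmm2` fit from [fit_gmm2()].
#' @param ... Unused.
#' @return A one-row tibble with `loglik`, `n_iter`, `converged`,
#'   `degenerate` and `n`.
#' @export
glance.gmm2 <- function(x, ...) {
  tibble(
    loglik = x$loglik,
    n_iter = x$n_iter,
    converged = x$converged,
    degenerate = isTRUE(x$degenerate),
    n = x$n
  )
}

#' Mixture density of a fitted gmm2
#'
#' @param fit A `gmm2` fit.
#' @param x Points at which to evaluate.
#' @return `w1 * N(x|mu1,sigma1) + w2 * N(x|mu2,sigma2)`.
#' @export
gmm2_density <- function(fit, x) {
  fit$w[1] * dnorm(x, fit$mu[1], fit$sigma[1]) + fit$w[2] * dnorm(x, fit$mu[2], fit$sigma[2])
}

#' Upper-tail p-value under the standard normal
#'
#' The conservative route: each z-score is referred to N(0, 1).
#'
#' @param z Numeric vector of z-scores.
#' @return `P(Z >= z)` under the standard normal.
#' @export
pvalue_single <- function(z) {
  pnorm(z, lower.tail = FALSE)
}

#' Upper-tail p-value under the background mixture component
#'
#' Refers each z-score to the smaller-mean (background) Gaussian of a
#' fitted two-component mixture: `p = 1 - Phi((z - mu1) / sigma1)`. With a
#' degenerate fit the mixture route is unavailable and the standard-normal
#' p-value is returned with a warning.
#'
#' @param z Numeric vector of z-scores.
#' @param fit A `gmm2` fit from [fit_gmm2()].
#' @return Upper-tail probabilities under `N(mu1, sigma1)`.
#' @export
pvalue_mixture <- function(z, fit) {
  if (!inherits(fit, "gmm2")) abort("`fit` must come from fit_gmm2()")
  if (isTRUE(fit$degenerate)) {
    warn("mixture fit is degenerate; falling back to the standard-normal p-value")
    return(pvalue_single(z))
  }
  pnorm(z, mean = fit$mu[1], sd = fit$sigma[1], lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), order-preserving on the
#' original index and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values of the same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Attach p-values, FDR and target flags to a score table
#'
#' Fits the two-component mixture on the z-scores and adds both significance
#' routes: `p_single`/`fdr_single` (standard normal) and
#' `p_mixture`/`fdr_mixture` (background component), plus target flags at
#' `fdr_threshold`.
#'
#' @param scores A score table from [tip_score()] (needs a `zscore` column).
#' @param fdr_threshold FDR threshold for the `is_target_*` flags; default
#'   0.05.
#' @param fit Optionally a pre-computed `gmm2` fit; fitted from the z-scores
#'   when `NULL`.
#' @param ... Passed to [fit_gmm2()].
#' @return The score table with columns `p_single`, `fdr_single`,
#'   `p_mixture`, `fdr_mixture`, `is_target_single`, `is_target_mixture`,
#'   and the fit in `attr(, "fit")`.
#' @export
score_significance <- function(scores, fdr_threshold = 0.05, fit = NULL, ...) {
  if (!is.data.frame(scores) || !"zscore" %in% names(scores)) {
    abort("`scores` must be a score table with a zscore column (see tip_score())")
  }
  if (is.null(fit)) fit <- fit_gmm2(scores$zscore, ...)
  out <- scores
  out$p_single <- pvalue_single(out$zscore)
  out$fdr_single <- bh_fdr(out$p_single)
  out$p_mixture <- pvalue_mixture(out$zscore, fit)
  out$fdr_mixture <- bh_fdr(out$p_mixture)
  out$is_target_single <- out$fdr_single < fdr_threshold
  out$is_target_mixture <- out$fdr_mixture < fdr_threshold
  attr(out, "fit") <- fit
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' Call significant target genes
#'
#' Selects transcripts whose FDR under the chosen route falls below the
#' threshold and sorts them by decreasing regulatory score (ties broken by
#' transcript id for reproducibility).
#'
#' @param score_table Output of [score_significance()].
#' @param fdr_threshold FDR threshold in (0, 1); default 0.05 (0.1 is a
#'   common lenient choice).
#' @param method `"mixture"` (default) or `"single"` — which p-value route
#'   drives the call.
#' @return The target rows of `score_table`, sorted by decreasing `score`.
#' @export
call_targets <- function(score_table, fdr_threshold = 0.05, method = c("mixture", "single")) {
  method <- match.arg(method)
  if (!is.numeric(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1) {
    abort("`fdr_threshold` must be in (0, 1]")
  }
  col <- paste0("fdr_", method)
  if (!col %in% names(score_table)) {
    abort(sprintf("`score_table` lacks the %s column; run score_significance() first", col))
  }
  score_table %>%
    filter(.data[[col]] < fdr_threshold) %>%
    arrange(desc(.data$score), .data$transcript_id)
}
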