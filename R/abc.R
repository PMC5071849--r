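# Rejection ABC over the 3-D site-pattern summary space, with a local-linear
# ridge-regression post-adjustment of accepted draws and leave-one-out
# cross-validation of the admixture-proportion estimator.

# standardize count rows by reference-table standard deviations; dimensions
# with zero variance are dropped (with a warning at the call site)
standardize_counts <- function(counts, sds, dims) {
  sweep(counts[, dims, drop = FALSE], 2L, sds[dims], "/")
}

obs_count_vector <- function(observed) {
  if (inherits(observed, "site_pattern_counts")) return(pattern_vector(observed))
  stopifnot(is.numeric(observed), length(observed) == 3L)
  stats::setNames(as.numeric(observed), PATTERN_CLASSES)
}

#' Rejection-step approximate Bayesian computation
#'
#' Standardizes the three pattern-count summaries by their reference-table
#' standard deviations, computes Euclidean distances from the observed
#' summary to every simulation, and retains the `round(tolerance * n_sims)`
#' closest draws (ties broken by simulation index). Summary dimensions with
#' zero variance across the reference table are dropped with a warning.
#'
#' @param observed A `site_pattern_counts` or numeric(3) (BBAA, ABBA, BABA).
#' @param ref A `parameter_draws` reference table.
#' @param tolerance Fraction of simulations to retain, in (0, 1].
#' @return A `posterior` object with the accepted draws (`accepted`), their
#'   distances, the observed summary and standardization constants;
#'   `adjusted` is filled by [ridge_adjust()].
#' @export
abc_reject <- function(observed, ref, tolerance) {
  stopifnot(inherits(ref, "parameter_draws"))
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance > 1)
    stopf("tolerance must lie in (0, 1]")
  obs <- obs_count_vector(observed)
  sds <- col_sds(ref$counts)
  dims <- which(sds > 0)
  if (length(dims) < 3L)
    warnf("abc_reject: dropping %d zero-variance summary dimension(s): %s",
          3L - length(dims),
          paste(PATTERN_CLASSES[setdiff(1:3, dims)], collapse = ", "))
  if (!length(dims)) stopf("abc_reject: all summary dimensions have zero variance")
  S <- standardize_counts(ref$counts, sds, dims)
  s_obs <- obs[dims] / sds[dims]
  d <- sqrt(rowSums(sweep(S, 2L, s_obs)^2))
  n_acc <- max(1L, as.integer(round(tolerance * ref$n_sims)))
  ord <- order(d)[seq_len(n_acc)]   # order() is stable: ties fall to lower index
  accepted <- cbind(index = ord, ref$params[ord, , drop = FALSE],
                    distance = d[ord])
  rownames(accepted) <- NULL
  structure(list(accepted = accepted, adjusted = NULL,
                 n_accepted = n_acc, tolerance = tolerance,
                 observed_counts = obs, observed_summary = s_obs,
                 summaries = S[ord, , drop = FALSE],
                 sds = sds, dims = dims, ref_n_sims = ref$n_sims),
            class = "posterior")
}

# weighted ridge fit with unpenalized intercept; returns coefficients and the
# weighted leave-one-out squared error (hat-matrix identity)
ridge_fit <- function(X, y, w, lambda) {
  sw <- sqrt(w)
  Xw <- cbind(1, X) * sw
  yw <- y * sw
  A <- crossprod(Xw) + diag(c(0, rep(lambda, ncol(X))), ncol(X) + 1L)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) return(NULL)
  beta <- drop(Ainv %*% crossprod(Xw, yw))
  h <- rowSums((Xw %*% Ainv) * Xw)
  r <- yw - drop(Xw %*% beta)
  loo <- sum((r / pmax(1 - h, 1e-12))^2)
  list(beta = beta, loo = loo)
}

#' Local-linear ridge adjustment of accepted ABC draws
#'
#' Within the accepted set, each parameter is regressed on the standardized
#' summaries centred at the observed summary, with Epanechnikov weights
#' 1 - (d/d_max)^2 and an L2 penalty on the slopes. The penalty is chosen per
#' parameter from `lambda_grid` by weighted leave-one-out error, and each
#' accepted draw is shifted by its fitted regression component:
#' adjusted = raw - (summary - observed)' beta. Raw draws are kept alongside.
#' Adjusted alpha values outside [0, 1] are retained and their count flagged.
#'
#' @param post A `posterior` from [abc_reject()].
#' @param lambda_grid Positive ridge penalties to choose among.
#' @return The `posterior` with `adjusted` filled (data.frame of adjusted
#'   parameters), `lambda` (chosen per parameter), `ridge_beta` (coefficient
#'   matrix) and `n_alpha_out_of_support`.
#' @export
ridge_adjust <- function(post, lambda_grid = c(1e-4, 1e-3, 1e-2)) {
  stopifnot(inherits(post, "posterior"))
  if (post$n_accepted < 10L) stopf("ridge_adjust needs >= 10 accepted draws")
  if (any(lambda_grid <= 0)) stopf("ridge penalties must be positive")
  X <- sweep(post$summaries, 2L, post$observed_summary)
  d <- post$accepted$distance
  delta <- max(d)
  w <- if (delta == 0) rep(1, length(d)) else 1 - (d / delta)^2
  w <- pmax(w, 0)
  if (all(w == 0)) w <- rep(1, length(d))

  pars <- c("alpha", "t1", "t2")
  adjusted <- post$accepted[, pars, drop = FALSE]
  lambda_sel <- stats::setNames(rep(NA_real_, length(pars)), pars)
  betas <- matrix(NA_real_, ncol(X) + 1L, length(pars),
                  dimnames = list(NULL, pars))
  failed <- FALSE
  for (p in pars) {
    y <- post$accepted[[p]]
    best <- NULL
    for (lam in sort(lambda_grid)) {
      fit <- ridge_fit(X, y, w, lam)
      if (is.null(fit)) next
      if (is.null(best) || fit$loo < best$loo) { best <- fit; best$lambda <- lam }
    }
    if (is.null(best)) { failed <- TRUE; break }
    adjusted[[p]] <- y - drop(X %*% best$beta[-1L])
    lambda_sel[p] <- best$lambda
    betas[, p] <- best$beta
  }
  if (failed) {
    warnf("ridge_adjust: singular weighted design at all penalties; falling back to rejection-only posterior")
    post$adjusted <- post$accepted[, pars, drop = FALSE]
    post$adjustment_failed <- TRUE
    return(post)
  }
  post$adjusted <- adjusted
  post$lambda <- lambda_sel
  post$ridge_beta <- betas
  post$weights <- w
  post$n_alpha_out_of_support <- sum(adjusted$alpha < 0 | adjusted$alpha > 1)
  post$adjustment_failed <- FALSE
  post
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf("ABC posterior: %d/%d draws accepted (tolerance %.4g)\n",
              x$n_accepted, x$ref_n_sims, x$tolerance))
  a <- if (!is.null(x$adjusted)) x$adjusted$alpha else x$accepted$alpha
  lab <- if (!is.null(x$adjusted)) "adjusted" else "rejection-only"
  cat(sprintf("  alpha (%s): mean %.3f, 90%% interval [%.3f, %.3f]\n",
              lab, mean(a), stats::quantile(a, 0.05), stats::quantile(a, 0.95)))
  if (!is.null(x$n_alpha_out_of_support) && x$n_alpha_out_of_support > 0)
    cat(sprintf("  %d adjusted alpha draw(s) outside [0, 1] (retained)\n",
                x$n_alpha_out_of_support))
  invisible(x)
}

#' Posterior probability of at least a given minority-ancestry fraction
#'
#' Fraction of posterior alpha draws (adjusted when available) with
#' 1 - alpha >= threshold, i.e. at least `threshold` ancestry from the
#' minority source (aurochs), reported as a percentage.
#'
#' @param post A `posterior`.
#' @param threshold Minimum minority-ancestry fraction (e.g. 0.01).
#' @return Percentage in [0, 100].
#' @export
posterior_probability <- function(post, threshold) {
  stopifnot(inherits(post, "posterior"))
  a <- if (!is.null(post$adjusted)) post$adjusted$alpha else post$accepted$alpha
  if (!length(a)) stopf("empty posterior")
  100 * mean((1 - a) >= threshold)
}

#' Leave-one-out cross-validation of the ABC alpha estimator
#'
#' For each of `n_cv` randomly selected simulations, treats its counts as the
#' observed data, reruns rejection + ridge adjustment against the remaining
#' reference table, and records the posterior-mean alpha. The prediction
#' error is the standardized form
#' \deqn{E_{pred} = \sum_i (\hat\alpha_i - \alpha_i)^2 / (n_{cv} \cdot Var(\alpha))}
#' with Var(alpha) taken over the full reference table, i.e. squared error in
#' units of the prior standard deviation.
#'
#' @param ref A `parameter_draws` reference table.
#' @param n_cv Number of held-out simulations (>= 2).
#' @param tolerance ABC tolerance used for each held-out run.
#' @param seed Integer seed for selecting held-out simulations.
#' @param lambda_grid Ridge penalties, passed to [ridge_adjust()].
#' @return A `cv_result`: n_cv, tolerance, per-simulation estimates and
#'   `prediction_error`.
#' @export
cv4abc <- function(ref, n_cv, tolerance, seed = 1L,
                   lambda_grid = c(1e-4, 1e-3, 1e-2)) {
  stopifnot(inherits(ref, "parameter_draws"))
  if (!is_count(n_cv) || n_cv < 2L) stopf("n_cv must be an integer >= 2")
  if (n_cv > ref$n_sims) stopf("n_cv exceeds the number of simulations")
  idx <- with_seed(seed, sample.int(ref$n_sims, n_cv))
  est <- numeric(n_cv)
  for (i in seq_len(n_cv)) {
    j <- idx[i]
    sub <- ref
    sub$params <- ref$params[-j, , drop = FALSE]
    sub$counts <- ref$counts[-j, , drop = FALSE]
    sub$n_sims <- ref$n_sims - 1L
    post <- abc_reject(ref$counts[j, ], sub, tolerance)
    post <- ridge_adjust(post, lambda_grid)
    est[i] <- mean(post$adjusted$alpha)
  }
  truth <- ref$params$alpha[idx]
  pe <- sum((est - truth)^2) / (n_cv * stats::var(ref$params$alpha))
  structure(list(n_cv = as.integer(n_cv), tolerance = tolerance,
                 estimates = data.frame(index = idx, true_alpha = truth,
                                        est_alpha = est),
                 prediction_error = pe),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv4abc: %d held-out simulations, tolerance %.4g\n",
              x$n_cv, x$tolerance))
  cat(sprintf("  standardized prediction error: %.4f s.d. units\n",
              x$prediction_error))
  invisible(x)
}

#' Dump an ABC posterior as TSV
#'
#' Columns: draw index, raw and adjusted parameters, distance.
#' @param post A `posterior`.
#' @param path Output TSV path.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "posterior"))
  tab <- data.frame(draw = post$accepted$index,
                    raw_alpha = post$accepted$alpha,
                    raw_t1 = post$accepted$t1, raw_t2 = post$accepted$t2,
                    distance = post$accepted$distance)
  if (!is.null(post$adjusted)) {
    tab$adjusted_alpha <- post$adjusted$alpha
    tab$adjusted_t1 <- post$adjusted$t1
    tab$adjusted_t2 <- post$adjusted$t2
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
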