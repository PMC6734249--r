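#' Multinomial log-likelihood ratio of the bound profile versus uniform
#'
#' Under binding, the spatial distribution of cuts at a site follows the
#' footprint profile `lambda`; without binding it is uniform (1/S). The
#' multinomial coefficient (`R!` over the `X_s!`) is identical in both
#' likelihoods, so the ratio reduces to `sum_s X_s (log lambda_s - log(1/S))`
#' and no factorial is ever materialised.
#'
#' @param X non-negative count vector (length S)
#' @param lambda strictly positive probability vector (length S)
#' @return log likelihood ratio (bound vs. uniform null)
#' @export
multinomial_log_ratio <- function(X, lambda) {
  if (length(X) != length(lambda)) stopf("X and lambda lengths differ")
  if (any(X < 0)) stopf("negative counts in X")
  if (any(lambda <= 0)) stopf("lambda must be strictly positive")
  S <- length(lambda)
  sum(X * (log(lambda) + log(S)))
}

nb_logpmf <- function(R, comp) {
  if (isTRUE(comp$poisson)) dpois(R, comp$mean, log = TRUE)
  else dnbinom(R, mu = comp$mean, size = comp$size, log = TRUE)
}

nb_from_moments <- function(R, w = NULL, size_floor = 0.05) {
  if (is.null(w)) w <- rep(1, length(R))
  sw <- sum(w)
  if (sw <= 0) return(list(mean = mean(R) + 1e-8, size = 1, poisson = FALSE))
  m <- sum(w * R) / sw
  v <- sum(w * (R - m)^2) / sw
  m <- max(m, 1e-8)
  if (v > m) {
    list(mean = m, size = max(m^2 / (v - m), size_floor), poisson = FALSE)
  } else {
    # under-dispersed responsibilities: fall back to Poisson
    list(mean = m, size = NA_real_, poisson = TRUE)
  }
}

#' Fit the two-component footprint mixture on a cut matrix
#'
#' Reimplements the bimodal bound/unbound clustering model used for digital
#' footprinting: per site, the read total R follows a negative binomial
#' (separate components for bound and unbound) and, given R, the cuts are
#' multinomial over the `S = 2W` strand-specific positions -- the footprint
#' profile `lambda` when bound, uniform when not. Fitting is plain EM; the
#' forward and reverse count matrices are concatenated column-wise so the
#' model sees strand-specific structure. Initialisation is deterministic:
#' `lambda` from the aggregate profile of the top half of sites by read
#' total, `pi = 0.1`, both NB components from global moments.
#'
#' @param m a `CutMatrix` (or a plain matrix of per-site counts, columns =
#'   model positions)
#' @param pseudocount Dirichlet-style pseudocount on lambda updates
#'   (default 1)
#' @param max_iter maximum EM iterations (default 200)
#' @param tol absolute log-likelihood change at convergence (default 1e-6)
#' @return a `FootprintModel`: list with S, W, lambda, pi, nb_bound,
#'   nb_null, loglik_trace, converged, responsibilities
#' @export
fit_footprint_model <- function(m, pseudocount = 1, max_iter = 200L,
                                tol = 1e-6) {
  X <- model_counts(m)
  S <- ncol(X)
  R <- rowSums(X)
  if (sum(R) == 0) stopf("degenerate input: cut matrix is all zero")
  if (sum(R > 0) < 20L) {
    stopf("need >= 20 sites with nonzero reads to fit the mixture (have %d)",
          sum(R > 0))
  }
  n <- nrow(X)
  log_unif <- -log(S)
  # deterministic init (no RNG): aggregate of the high-coverage half
  top <- R >= stats::median(R)
  lambda <- (colSums(X[top, , drop = FALSE]) + pseudocount)
  lambda <- pmax(lambda / sum(lambda), 1e-8)
  lambda <- lambda / sum(lambda)
  pi <- 0.1
  nb_b <- nb_from_moments(R)
  nb_n <- nb_b
  trace <- numeric(0)
  converged <- FALSE
  z <- rep(0.5, n)
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    la <- log(pi) + nb_logpmf(R, nb_b) + as.vector(X %*% log(lambda))
    lb <- log1p(-pi) + nb_logpmf(R, nb_n) + R * log_unif
    ll <- sum(logsumexp2(la, lb))
    if (length(trace) && ll < trace[length(trace)] - 1e-9) {
      # the moment-based NB update is not an exact M-step; if it ever stops
      # improving the likelihood, keep the previous (better) parameters
      lambda <- prev$lambda; pi <- prev$pi
      nb_b <- prev$nb_b; nb_n <- prev$nb_n; z <- prev$z
      converged <- TRUE
      break
    }
    z <- plogis(la - lb)
    trace <- c(trace, ll)
    if (iter > 1L && abs(ll - trace[length(trace) - 1L]) < tol) {
      converged <- TRUE
      break
    }
    prev <- list(lambda = lambda, pi = pi, nb_b = nb_b, nb_n = nb_n, z = z)
    # M-step
    lambda <- (colSums(z * X) + pseudocount) / (sum(z * R) + S * pseudocount)
    lambda <- pmax(lambda, 1e-8)
    lambda <- lambda / sum(lambda)
    pi <- min(max(mean(z), 1e-4), 1 - 1e-4)
    nb_b <- nb_from_moments(R, z)
    nb_n <- nb_from_moments(R, 1 - z)
  }
  if (!converged) {
    warning(sprintf("EM did not converge in %d iterations (last delta %.3g)",
                    max_iter, abs(diff(utils::tail(trace, 2)))))
  }
  structure(list(S = S, W = S %/% 2L, lambda = lambda, pi = pi,
                 nb_bound = nb_b, nb_null = nb_n, loglik_trace = trace,
                 converged = converged, responsibilities = z),
            class = "FootprintModel")
}

model_counts <- function(m) {
  if (inherits(m, "CutMatrix")) cbind(m$forward, m$reverse)
  else if (is.matrix(m)) m
  else stopf("expected a CutMatrix or a counts matrix")
}

#' @export
print.FootprintModel <- function(x, ...) {
  cat(sprintf(paste0("FootprintModel: S = %d positions, pi = %.3f, ",
                     "NB bound mean %.1f / null mean %.1f, %d EM iterations",
                     " (%sconverged)\n"),
              x$S, x$pi, x$nb_bound$mean, x$nb_null$mean,
              length(x$loglik_trace), if (x$converged) "" else "not "))
  invisible(x)
}

#' Posterior binding log-odds per motif site
#'
#' For each site, `log_odds = logit(pi) + [log NB(R; bound) - log NB(R;
#' null)] + multinomial_log_ratio(X, lambda)` and the posterior binding
#' probability is its logistic transform. Log-odds are clipped to +/-700 so
#' the transform stays finite.
#'
#' @param model a fitted `FootprintModel`
#' @param m the `CutMatrix` (or counts matrix) to score
#' @return data.frame with site_id (plus site coordinates when available),
#'   R, log_odds, posterior; rows in site order
#' @export
score_sites <- function(model, m) {
  stopifnot(inherits(model, "FootprintModel"))
  X <- model_counts(m)
  if (ncol(X) != model$S) {
    stopf("matrix has %d columns but model expects S = %d", ncol(X), model$S)
  }
  R <- rowSums(X)
  log_odds <- qlogis(model$pi) +
    nb_logpmf(R, model$nb_bound) - nb_logpmf(R, model$nb_null) +
    as.vector(X %*% (log(model$lambda) + log(model$S)))
  log_odds <- pmin(pmax(log_odds, -700), 700)
  out <- data.frame(site_id = rownames(X) %||% sprintf("site_%04d",
                                                       seq_len(nrow(X))),
                    R = R, log_odds = log_odds,
                    posterior = plogis(log_odds),
                    stringsAsFactors = FALSE)
  if (inherits(m, "CutMatrix")) {
    out <- cbind(m$sites[, intersect(c("chrom", "start", "end", "strand"),
                                     names(m$sites)), drop = FALSE], out)
    out$site_id <- m$sites$site_id
  }
  rownames(out) <- NULL
  out
}

#' Serialise a FootprintModel to JSON
#' @param model a `FootprintModel`
#' @param path output path
#' @return invisibly, the path
#' @export
write_model_json <- function(model, path) {
  # 17 significant digits round-trip IEEE doubles exactly, so downstream
  # stages reloading the model reproduce in-memory results byte-for-byte
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), na = "null")
  invisible(path)
}

#' Read a FootprintModel back from JSON
#' @param path JSON path written by [write_model_json()]
#' @return a `FootprintModel`
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nb_bound <- as.list(x$nb_bound)
  x$nb_null <- as.list(x$nb_null)
  structure(x, class = "FootprintModel")
}
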