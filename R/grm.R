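# Samejima graded response model: response functions, MML-EM estimation,
# Fisher information, and EAP ability scoring. Logistic parameterization
# a * (theta - b_k) with no 1.7 scaling constant, so that a dichotomous
# item's information integral over the latent range equals its
# discrimination.

#' GRM boundary probability
#'
#' Probability that a response falls at or above the category bounded by
#' threshold `b_k`: the two-parameter logistic curve
#' \deqn{P^*_k(\theta) = 1 / (1 + e^{-a(\theta - b_k)}).}
#' No scaling constant is applied to the logistic slope.
#'
#' @param a Discrimination (> 0).
#' @param b_k Threshold (extremity) parameter.
#' @param theta Latent trait value(s).
#' @return Probability vector the length of `theta`.
#' @export
#' @examples
#' boundary_prob(2, 0.5, 0.5)  # 0.5 at the threshold
boundary_prob <- function(a, b_k, theta) {
  stopifnot(a > 0)
  plogis(a * (theta - b_k))
}

#' GRM category probabilities
#'
#' For an item with ordered thresholds `b` (length m, giving m + 1
#' categories), returns the probability of each category at each `theta`:
#' \eqn{P_k = P^*_k - P^*_{k+1}} with \eqn{P^*_0 = 1} and
#' \eqn{P^*_{m+1} = 0}.
#'
#' @param a Discrimination (> 0).
#' @param b Strictly increasing numeric vector of thresholds.
#' @param theta Latent trait value(s).
#' @return Matrix `length(theta)` x `(length(b) + 1)`; rows sum to 1.
#' @export
category_probs <- function(a, b, theta) {
  stopifnot(a > 0, length(b) >= 1, !is.unsorted(b, strictly = TRUE))
  Pst <- vapply(b, function(bk) plogis(a * (theta - bk)), numeric(length(theta)))
  Pst <- matrix(Pst, nrow = length(theta))
  Ps <- cbind(1, Pst, 0)
  Ps[, seq_len(ncol(Ps) - 1L), drop = FALSE] - Ps[, -1L, drop = FALSE]
}

#' GRM item information function
#'
#' Fisher information about the latent trait carried by one graded item:
#' \deqn{I(\theta) = a^2 \sum_k \frac{(w_k - w_{k+1})^2}{P^*_k - P^*_{k+1}},
#'   \quad w_k = P^*_k (1 - P^*_k),}
#' with \eqn{w_0 = w_{m+1} = 0}. For a dichotomous item this reduces to
#' \eqn{a^2 P^*(1 - P^*)}, maximal at \eqn{\theta = b} with value
#' \eqn{a^2/4}.
#'
#' @inheritParams category_probs
#' @return Numeric vector of information values, one per `theta`.
#' @export
item_information <- function(a, b, theta) {
  stopifnot(a > 0, length(b) >= 1, !is.unsorted(b, strictly = TRUE))
  Pst <- vapply(b, function(bk) plogis(a * (theta - bk)), numeric(length(theta)))
  Pst <- matrix(Pst, nrow = length(theta))
  Ps <- cbind(1, Pst, 0)
  w <- Ps * (1 - Ps)
  num <- (w[, seq_len(ncol(w) - 1L), drop = FALSE] - w[, -1L, drop = FALSE])^2
  den <- Ps[, seq_len(ncol(Ps) - 1L), drop = FALSE] - Ps[, -1L, drop = FALSE]
  contrib <- ifelse(den > 1e-300, num / den, 0)
  a^2 * rowSums(contrib)
}

#' Integrated item information
#'
#' Trapezoid integral of [item_information()] over a latent-trait range on a
#' dense fixed grid. For a dichotomous item the closed form is
#' \eqn{a (P^*(hi) - P^*(lo))}, which approaches the discrimination `a` as
#' the range widens -- the identity that makes integrated information
#' directly comparable to discrimination.
#'
#' @inheritParams category_probs
#' @param range Integration range, default `c(-10, 10)`.
#' @param n_grid Number of grid points (default 2001; the integral is stable
#'   to well under 1e-3 at this density for discriminations in the range met
#'   in practice).
#' @return Scalar integrated information.
#' @export
#' @examples
#' item_information_integral(3.70, 1.30)  # ~= 3.70
item_information_integral <- function(a, b, range = c(-10, 10), n_grid = 2001L) {
  th <- seq(range[1], range[2], length.out = n_grid)
  I <- item_information(a, b, th)
  h <- th[2] - th[1]
  sum((I[-1] + I[-length(I)]) / 2) * h
}

#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with standard-normal prior weights (normalized to sum
#' to 1), used for the EM E-step and EAP scoring.
#'
#' @param n_nodes Number of nodes (default 61).
#' @param range Node range (default `c(-6, 6)`).
#' @return List with `nodes` and `weights`.
#' @export
quadrature_spec <- function(n_nodes = 61L, range = c(-6, 6)) {
  nodes <- seq(range[1], range[2], length.out = n_nodes)
  w <- dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' AIC and BIC from a marginal log-likelihood
#'
#' @param loglik Marginal log-likelihood.
#' @param p Number of free parameters.
#' @param n Number of subjects.
#' @return Named vector `c(aic, bic)` with `aic = -2*loglik + 2*p` and
#'   `bic = -2*loglik + p*log(n)`.
#' @export
information_criteria <- function(loglik, p, n) {
  stopifnot(p >= 0, n >= 1)
  c(aic = -2 * loglik + 2 * p, bic = -2 * loglik + p * log(n))
}

# ---- internal M-step machinery -------------------------------------------

# par = c(log a, b_1, log-gaps d_2..d_m); enforces b strictly increasing.
# Clamped so that any par reachable during a line search maps to a valid,
# finite parameter point (a in [1e-3, 150], threshold gaps >= 1e-6).
.par_to_ab <- function(par) {
  a <- exp(min(max(par[1], -7), 5))
  m <- length(par) - 1L
  b <- min(max(par[2], -50), 50)
  if (m > 1L) {
    gaps <- pmax(exp(pmin(par[-(1:2)], 5)), 1e-6)
    b <- b + c(0, cumsum(gaps))
  }
  list(a = a, b = b)
}

.ab_to_par <- function(a, b) {
  m <- length(b)
  par <- c(log(a), b[1])
  if (m > 1L) par <- c(par, log(pmax(diff(b), 1e-4)))
  par
}

# lean category probabilities for the hot path (no validation)
.cat_probs <- function(a, b, nodes) {
  m <- length(b)
  Ps <- matrix(0, length(nodes), m + 2L)
  Ps[, 1L] <- 1
  for (k in seq_len(m)) Ps[, k + 1L] <- plogis(a * (nodes - b[k]))
  Ps[, seq_len(m + 1L), drop = FALSE] - Ps[, -1L, drop = FALSE]
}

# expected-count negative log-likelihood for one item; r is Q x K
.item_nll <- function(par, r, nodes) {
  if (!all(is.finite(par))) return(1e10)
  ab <- .par_to_ab(par)
  P <- .cat_probs(ab$a, ab$b, nodes)
  -sum(r * log(P + 1e-300))
}

.item_nll_grad <- function(par, r, nodes) {
  if (!all(is.finite(par))) return(rep(0, length(par)))
  ab <- .par_to_ab(par)
  a <- ab$a; b <- ab$b
  m <- length(b); K <- m + 1L
  Pst <- matrix(0, length(nodes), m)
  for (k in seq_len(m)) Pst[, k] <- plogis(a * (nodes - b[k]))
  Ps <- cbind(1, Pst, 0)
  P <- Ps[, 1:K, drop = FALSE] - Ps[, -1L, drop = FALSE]
  ratio <- r / pmax(P, 1e-12)
  # dNLL/dz_k = (r_{k-1}/P_{k-1} - r_k/P_k) * P*_k (1 - P*_k), columns = categories
  grad_b <- numeric(m); grad_a <- 0
  for (k in seq_len(m)) {
    s <- Pst[, k] * (1 - Pst[, k])
    g <- (ratio[, k] - ratio[, k + 1L]) * s
    grad_a <- grad_a + sum(g * (nodes - b[k]))
    grad_b[k] <- -a * sum(g)
  }
  out <- numeric(length(par))
  out[1] <- a * grad_a
  out[2] <- sum(grad_b)
  if (m > 1L)
    for (j in 2:m) out[j + 1L] <- exp(par[j + 1L]) * sum(grad_b[j:m])
  out
}

# per-item starting values: a = 1, b at prior quantiles of observed
# cumulative category frequencies
.start_par <- function(x, K) {
  phat <- vapply(seq_len(K - 1L), function(k) mean(x >= k, na.rm = TRUE),
                 numeric(1))
  b <- qnorm(pmin(pmax(1 - phat, 0.02), 0.98))
  b <- cummax(b + seq_along(b) * 1e-3)  # enforce strict order
  .ab_to_par(1, b)
}

#' Fit a graded response model by marginal maximum likelihood
#'
#' EM estimation of Samejima's graded response model under a standard-normal
#' latent prior. The E-step computes posterior weights on a fixed quadrature
#' grid; the M-step maximizes each item's expected complete-data
#' log-likelihood over (discrimination, ordered thresholds), with thresholds
#' reparameterized as \eqn{b_1, b_1 + e^{\delta_2}, \ldots} to keep them
#' ordered. Missing responses drop out of the subject's likelihood product
#' (missing-at-random). Estimation is deterministic given the data and
#' starting values.
#'
#' @param data A `perio_resp` object (see [chart_to_response_matrix()]) or a
#'   plain integer matrix of category codes 0..(K-1) with `NA` for missing,
#'   subjects in rows.
#' @param quad Quadrature grid, as from [quadrature_spec()].
#' @param tol EM convergence tolerance on the change in marginal
#'   log-likelihood (default 1e-4).
#' @param max_iter Maximum EM iterations (default 200).
#' @param m_step_maxit BFGS iterations per item per M-step (default 8; the
#'   warm-started partial M-step is a generalized EM and preserves the
#'   likelihood ascent).
#' @return Object of class `grm_fit`: list with `items` (data frame of
#'   `label`, `a`, `b1`, `b2`, ..., `n_categories` plus any site metadata),
#'   `params` (per-item list of `a`, `b`), `loglik`, `n`, `p`, `aic`, `bic`,
#'   `converged`, `n_iterations`, `quad`, and the response metadata.
#' @export
fit_grm <- function(data, quad = quadrature_spec(), tol = 1e-4,
                    max_iter = 200L, m_step_maxit = 8L) {
  if (inherits(data, "perio_resp")) {
    X <- data$responses
    item_meta <- data$items
  } else {
    X <- as.matrix(data)
    storage.mode(X) <- "integer"
    item_meta <- data.frame(label = colnames(X) %||% paste0("item", seq_len(ncol(X))),
                            stringsAsFactors = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- item_meta$label
  n <- nrow(X); J <- ncol(X)
  if (n < 1L || J < 1L) stop("need at least one subject and one item")

  # observed category structure; every category 0..K-1 must be occupied
  K <- integer(J)
  for (j in seq_len(J)) {
    obs <- X[, j][!is.na(X[, j])]
    if (!length(obs)) stop("item ", colnames(X)[j], " has no observed responses")
    cats <- sort(unique(obs))
    Kj <- max(obs) + 1L
    if (length(cats) < 2L || !identical(cats, 0:(Kj - 1L)))
      stop("category collapse needed for item '", colnames(X)[j],
           "': observed categories {", paste(cats, collapse = ","),
           "} leave empty cells; merge categories first ",
           "(see collapse_empty_categories())")
    K[j] <- Kj
  }

  nodes <- quad$nodes; wq <- quad$weights
  Q <- length(nodes)

  pars <- lapply(seq_len(J), function(j) .start_par(X[, j], K[j]))
  obs_idx <- lapply(seq_len(J), function(j) which(!is.na(X[, j])))

  loglik_trace <- numeric(0)
  loglik_prev <- -Inf
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    # E-step: log joint over quadrature nodes
    LL <- matrix(0, Q, n)
    for (j in seq_len(J)) {
      ab <- .par_to_ab(pars[[j]])
      logP <- log(.cat_probs(ab$a, ab$b, nodes) + 1e-300)
      idx <- obs_idx[[j]]
      LL[, idx] <- LL[, idx] + logP[, X[idx, j] + 1L, drop = FALSE]
    }
    cmax <- apply(LL, 2, max)
    A <- exp(sweep(LL, 2, cmax, "-")) * wq
    marg <- colSums(A)
    loglik <- sum(log(marg) + cmax)
    post <- sweep(A, 2, marg, "/")

    loglik_trace <- c(loglik_trace, loglik)
    if (is.finite(loglik_prev) && abs(loglik - loglik_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    loglik_prev <- loglik

    # M-step: per-item expected counts then warm-started BFGS
    for (j in seq_len(J)) {
      idx <- obs_idx[[j]]
      xj <- X[idx, j]
      r <- matrix(0, Q, K[j])
      for (k in 0:(K[j] - 1L)) {
        cols <- idx[xj == k]
        if (length(cols))
          r[, k + 1L] <- rowSums(post[, cols, drop = FALSE])
      }
      opt <- tryCatch(
        optim(pars[[j]], .item_nll, .item_nll_grad, r = r, nodes = nodes,
              method = "BFGS", control = list(maxit = m_step_maxit)),
        error = function(e) NULL)
      if (!is.null(opt) &&
          opt$value <= .item_nll(pars[[j]], r, nodes) + 1e-10)
        pars[[j]] <- opt$par
    }
  }

  ab_list <- lapply(pars, .par_to_ab)
  m_max <- max(K) - 1L
  bmat <- t(vapply(ab_list, function(ab) {
    c(ab$b, rep(NA_real_, m_max - length(ab$b)))
  }, numeric(m_max)))
  items <- item_meta
  items$a <- vapply(ab_list, `[[`, numeric(1), "a")
  for (k in seq_len(m_max)) items[[paste0("b", k)]] <- bmat[, k]
  items$n_categories <- K

  p <- sum(K)  # per item: 1 discrimination + (K-1) thresholds = K
  ic <- information_criteria(loglik, p, n)

  structure(list(items = items,
                 params = ab_list,
                 loglik = loglik,
                 loglik_trace = loglik_trace,
                 n = n, p = p,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 converged = converged,
                 n_iterations = iter,
                 quad = quad,
                 n_categories = K,
                 labels = colnames(X)),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat("Graded response model fit:", length(x$params), "items,",
      x$n, "subjects\n")
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f  (%s in %d EM iterations)\n",
              x$loglik, x$aic, x$bic,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Collapse empty response categories
#'
#' Recodes each item's observed categories onto a contiguous 0..(k-1) scale,
#' merging away categories never observed. Use when [fit_grm()] raises a
#' category-collapse error (e.g. a site where no patient reaches the top
#' severity category).
#'
#' @param data A `perio_resp` object or integer response matrix.
#' @return Object of the same type with recoded responses and updated
#'   category counts.
#' @export
collapse_empty_categories <- function(data) {
  is_resp <- inherits(data, "perio_resp")
  X <- if (is_resp) data$responses else as.matrix(data)
  for (j in seq_len(ncol(X))) {
    obs <- sort(unique(X[, j][!is.na(X[, j])]))
    X[, j] <- match(X[, j], obs) - 1L
  }
  if (is_resp) {
    data$responses <- X
    data$n_categories <- vapply(seq_len(ncol(X)), function(j)
      max(X[, j], na.rm = TRUE) + 1L, integer(1))
    data
  } else X
}

#' Expected a posteriori (EAP) ability
#'
#' Posterior mean and standard deviation of the latent trait given a
#' response pattern, under the standard-normal prior, computed on a dense
#' grid. Missing responses are skipped; an all-missing pattern returns the
#' prior (mean 0).
#'
#' @param fit A `grm_fit`.
#' @param pattern Integer vector of category codes (length = number of
#'   items, `NA` allowed), or a matrix/data frame with one pattern per row.
#' @param grid_n,range Scoring grid density and range (defaults 201 nodes on
#'   `c(-6, 6)`; denser than the EM grid so posterior means are stable to
#'   ~1e-4).
#' @return Data frame with columns `theta` and `se`, one row per pattern.
#' @export
eap_ability <- function(fit, pattern, grid_n = 201L, range = c(-6, 6)) {
  stopifnot(inherits(fit, "grm_fit"))
  P <- if (is.matrix(pattern) || is.data.frame(pattern)) as.matrix(pattern)
       else matrix(pattern, nrow = 1L)
  J <- length(fit$params)
  if (ncol(P) != J) stop("pattern must have one entry per item (", J, ")")
  for (j in seq_len(J)) {
    bad <- !is.na(P[, j]) & (P[, j] < 0 | P[, j] >= fit$n_categories[j])
    if (any(bad)) stop("category code out of range for item ", fit$labels[j])
  }
  th <- seq(range[1], range[2], length.out = grid_n)
  logw <- dnorm(th, log = TRUE)
  LL <- matrix(logw, nrow = grid_n, ncol = nrow(P))
  for (j in seq_len(J)) {
    ab <- fit$params[[j]]
    logP <- log(pmax(category_probs(ab$a, ab$b, th), 1e-300))
    idx <- which(!is.na(P[, j]))
    if (length(idx))
      LL[, idx] <- LL[, idx] + logP[, P[idx, j] + 1L, drop = FALSE]
  }
  A <- exp(sweep(LL, 2, apply(LL, 2, max), "-"))
  Z <- colSums(A)
  m1 <- colSums(A * th) / Z
  m2 <- colSums(A * th^2) / Z
  data.frame(theta = m1, se = sqrt(pmax(m2 - m1^2, .Machine$double.eps)))
}

#' Ability quick-reference table
#'
#' Enumerates every possible response pattern of a fitted model and its EAP
#' ability -- the "quick reference" form in which a short partial-exam
#' protocol can be scored in the field without software -- plus an
#' aggregation by raw sum score giving the ability range per score.
#'
#' @param fit A `grm_fit`.
#' @param cap Maximum number of patterns to enumerate (default 729, i.e. six
#'   three-category items).
#' @return List with `patterns` (data frame: one row per pattern, item
#'   columns plus `sum_score`, `theta`, `se`) and `by_score` (data frame:
#'   `sum_score`, `n_patterns`, `theta_min`, `theta_mean`, `theta_max`).
#' @export
score_table <- function(fit, cap = 729L) {
  stopifnot(inherits(fit, "grm_fit"))
  K <- fit$n_categories
  n_pat <- prod(K)
  if (n_pat > cap)
    stop("pattern count ", n_pat, " exceeds cap ", cap,
         "; use sum-score scoring instead")
  grid <- do.call(expand.grid, c(lapply(K, function(k) 0:(k - 1L)),
                                 KEEP.OUT.ATTRS = FALSE))
  names(grid) <- fit$labels
  ab <- eap_ability(fit, as.matrix(grid))
  patterns <- cbind(grid,
                    sum_score = rowSums(grid),
                    theta = ab$theta, se = ab$se)
  agg <- do.call(rbind, lapply(split(patterns, patterns$sum_score), function(d) {
    data.frame(sum_score = d$sum_score[1], n_patterns = nrow(d),
               theta_min = min(d$theta), theta_mean = mean(d$theta),
               theta_max = max(d$theta))
  }))
  rownames(agg) <- NULL
  list(patterns = patterns, by_score = agg)
}
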