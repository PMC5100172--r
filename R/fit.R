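# Maximum-likelihood machinery for the cumulative-logit model.
#
# Parameterization used throughout:  logit P(Y <= k) = alpha_{k+1} - eta,
# with eta the linear predictor of the slopes.  Cutpoints are optimized
# unconstrained as (alpha_1, log(alpha_2 - alpha_1), ...), which keeps
# them strictly increasing by construction.  Rows are treated as
# independent given covariates (working independence); the participant-
# level clustering is handled by the permutation test, not the likelihood.

#' Encode transitional rows as a numeric design
#'
#' Builds the slope design matrix: dummy indicators for the non-reference
#' motor-level/distance codes, for baseline score levels 1..5 and for
#' autoregressive score levels 1..5 (reference level 0 each), plus an
#' optional treatment indicator.  Levels absent from `rows` produce no
#' column and are recorded in `dropped_levels`; if a factor's reference
#' level is absent, the smallest observed level becomes the reference
#' (also recorded).
#'
#' @param rows Long-format rows from [build_transitional_rows()].
#' @param include_treatment Add the `trt` indicator column?
#' @return List with elements `X` (matrix), `col_labels`, `y` (1-based
#'   outcome index), `outcome_levels`, `n`, and `dropped_levels`.
#' @export
encode_design <- function(rows, include_treatment = FALSE) {
  n <- nrow(rows)
  if (!n) stop("no rows to encode")
  y_obs <- sort(unique(rows$y_out))
  if (length(y_obs) < 2L) stop("outcome degenerate: single outcome category")

  lev_all <- lev_levels()
  lev_obs <- lev_all[lev_all %in% unique(rows$lev)]
  base_obs <- sort(unique(rows$y_base))
  auto_obs <- sort(unique(rows$y_auto))

  dropped <- list(
    lev = setdiff(lev_all, lev_obs),
    y_base = setdiff(0:5, base_obs),
    y_auto = setdiff(0:5, auto_obs),
    outcome = setdiff(0:5, y_obs))
  if (lev_obs[1L] != "C5.-1") dropped$lev_reference <- lev_obs[1L]
  if (base_obs[1L] != 0L) dropped$base_reference <- base_obs[1L]
  if (auto_obs[1L] != 0L) dropped$auto_reference <- auto_obs[1L]

  cols <- list()
  for (l in lev_obs[-1L]) cols[[paste0("lev:", l)]] <- as.numeric(rows$lev == l)
  for (b in base_obs[-1L]) cols[[paste0("base:", b)]] <- as.numeric(rows$y_base == b)
  for (a in auto_obs[-1L]) cols[[paste0("auto:", a)]] <- as.numeric(rows$y_auto == a)
  if (include_treatment) cols[["trt"]] <- as.numeric(rows$arm)

  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, n, 0)
  labels <- names(cols) %||% character(0)
  colnames(X) <- labels
  list(X = X, col_labels = labels, y = match(rows$y_out, y_obs),
       outcome_levels = as.integer(y_obs), n = n, dropped_levels = dropped)
}

#' Negative log-likelihood of a coefficient set on transitional rows
#'
#' Direct evaluation of \eqn{-\sum_i \log P(Y = y_i \mid x_i)} from a
#' fixed [coefficient_set()]; no fitting.  Useful for model comparison
#' and as the quantity the optimizer minimizes.
#'
#' @param coeffs A [coefficient_set()].
#' @param rows Long-format rows (need `lev, y_base, y_auto, y_out, arm`).
#' @return Non-negative scalar.
#' @export
neg_log_likelihood <- function(coeffs, rows) {
  pr <- predict_category_probabilities(coeffs, rows$lev, rows$y_base,
                                       rows$y_auto, rows$arm)
  idx <- match(rows$y_out, coeffs$outcome_levels)
  if (anyNA(idx)) stop("y_out outside the coefficient set's outcome levels")
  -sum(log(pmax(pr[cbind(seq_len(nrow(rows)), idx)], 1e-300)))
}

# Core optimizer on a prepared design.  theta = (alpha, beta).  The
# cumulative-logit log-likelihood is jointly concave in cutpoints and
# slopes, so damped Newton-Raphson with the analytic Hessian is the
# primary route (2-4 iterations on warm-started permutation refits);
# BFGS on the log-increment cutpoint reparameterization is the fallback
# when a Newton step fails.  Returns enough state for warm restarts.
fit_po_xy <- function(X, y, K, start = NULL, maxit = 500L,
                      gtol = 1e-6, reltol = 1e-12) {
  n <- length(y)
  p <- ncol(X)
  ncut <- K - 1L
  gtol_abs <- gtol * max(1, n)

  # per-category row index sets (small K, computed once)
  idx_hi <- lapply(seq_len(ncut), function(j) which(y == j))        # alpha_j is upper bound
  idx_lo <- lapply(seq_len(ncut), function(j) which(y == j + 1L))   # alpha_j is lower bound
  fin_hi <- y < K
  fin_lo <- y > 1L

  state <- function(theta) {
    alpha <- theta[seq_len(ncut)]
    eta <- if (p) drop(X %*% theta[ncut + seq_len(p)]) else numeric(n)
    u_hi <- c(alpha, Inf)[y] - eta
    u_lo <- c(-Inf, alpha)[y] - eta
    F_hi <- stats::plogis(u_hi)
    F_lo <- stats::plogis(u_lo)
    pr <- pmax(F_hi - F_lo, 1e-300)
    f_hi <- numeric(n); f_hi[fin_hi] <- F_hi[fin_hi] * (1 - F_hi[fin_hi])
    f_lo <- numeric(n); f_lo[fin_lo] <- F_lo[fin_lo] * (1 - F_lo[fin_lo])
    list(alpha = alpha, eta = eta, pr = pr,
         F_hi = F_hi, F_lo = F_lo, f_hi = f_hi, f_lo = f_lo,
         nll = -sum(log(pr)))
  }
  grad_of <- function(st) {
    rh <- st$f_hi / st$pr
    rl <- st$f_lo / st$pr
    g_alpha <- vapply(seq_len(ncut), function(j)
      -(sum(rh[idx_hi[[j]]]) - sum(rl[idx_lo[[j]]])), numeric(1))
    g_beta <- if (p) drop(crossprod(X, rh - rl)) else numeric(0)
    c(g_alpha, g_beta)
  }
  hess_of <- function(st) {
    # second derivatives of -log p wrt the two bound arguments
    rh <- st$f_hi / st$pr
    rl <- st$f_lo / st$pr
    fp_hi <- st$f_hi * (1 - 2 * st$F_hi)       # f'(u_hi)
    fp_lo <- st$f_lo * (1 - 2 * st$F_lo)
    A <- -fp_hi / st$pr + rh^2                  # d2/d u_hi^2
    B <- fp_lo / st$pr + rl^2                   # d2/d u_lo^2
    C <- -rh * rl                               # d2/d u_hi d u_lo
    H <- matrix(0, ncut + p, ncut + p)
    for (j in seq_len(ncut)) {
      H[j, j] <- sum(A[idx_hi[[j]]]) + sum(B[idx_lo[[j]]])
      if (j < ncut) {
        v <- sum(C[idx_lo[[j]]])                # rows with y = j+1: hi=j+1, lo=j
        H[j, j + 1L] <- H[j + 1L, j] <- v
      }
    }
    if (p) {
      w_eta <- A + B + 2 * C
      H[ncut + seq_len(p), ncut + seq_len(p)] <- crossprod(X, X * w_eta)
      for (j in seq_len(ncut)) {
        ih <- idx_hi[[j]]; il <- idx_lo[[j]]
        v <- numeric(p)
        if (length(ih)) v <- v + colSums(X[ih, , drop = FALSE] * (A[ih] + C[ih]))
        if (length(il)) v <- v + colSums(X[il, , drop = FALSE] * (B[il] + C[il]))
        H[j, ncut + seq_len(p)] <- H[ncut + seq_len(p), j] <- -v
      }
    }
    H
  }

  if (is.null(start) || length(start) != ncut + p) {
    cum <- cumsum(tabulate(y, K) / n)[seq_len(ncut)]
    cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
    start <- c(stats::qlogis(cum), numeric(p))
  }

  theta <- start
  st <- state(theta)
  ok <- FALSE
  for (it in seq_len(50L)) {
    g <- grad_of(st)
    if (max(abs(g)) <= gtol_abs) { ok <- TRUE; break }
    H <- hess_of(st)
    delta <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    stepped <- FALSE
    s <- 1
    for (h in 1:30) {
      cand <- theta - s * delta
      a <- cand[seq_len(ncut)]
      if (all(diff(a) > 0) || ncut == 1L) {
        st2 <- state(cand)
        if (is.finite(st2$nll) && st2$nll <= st$nll + 1e-12) {
          theta <- cand; st <- st2; stepped <- TRUE; break
        }
      }
      s <- s / 2
    }
    if (!stepped) break
  }
  if (!ok) {
    g <- grad_of(st)
    ok <- max(abs(g)) <= gtol_abs
  }

  if (!ok) {
    # fallback: quasi-Newton on (alpha_1, log-increments, beta)
    res <- fit_po_bfgs(X, y, K, theta, maxit, reltol)
    theta <- res$theta
    st <- state(theta)
  }

  grad_sup <- max(abs(grad_of(st)))
  alpha <- theta[seq_len(ncut)]
  beta <- if (p) stats::setNames(theta[ncut + seq_len(p)], colnames(X)) else numeric(0)
  list(theta = theta,
       alpha = alpha,
       beta = beta,
       logLik = -st$nll,
       grad_sup = grad_sup,
       converged = grad_sup <= gtol_abs,
       separation = (length(beta) && max(abs(beta)) > 30) || max(abs(alpha)) > 30)
}

# Standalone nll + analytic gradient at theta = (alpha, beta) on a
# prepared design; the formulas mirrored by the Newton closures above.
# Kept separate so tests can probe the gradient at arbitrary points.
po_nll_grad <- function(X, y, K, theta) {
  n <- length(y)
  p <- ncol(X)
  ncut <- K - 1L
  alpha <- theta[seq_len(ncut)]
  eta <- if (p) drop(X %*% theta[ncut + seq_len(p)]) else numeric(n)
  hi <- c(alpha, Inf)[y] - eta
  lo <- c(-Inf, alpha)[y] - eta
  pr <- pmax(stats::plogis(hi) - stats::plogis(lo), 1e-300)
  d_hi <- ifelse(is.finite(hi), stats::dlogis(hi), 0) / pr
  d_lo <- ifelse(is.finite(lo), stats::dlogis(lo), 0) / pr
  g_alpha <- vapply(seq_len(ncut), function(j)
    -(sum(d_hi[y == j]) - sum(d_lo[y == j + 1L])), numeric(1))
  g_beta <- if (p) drop(crossprod(X, d_hi - d_lo)) else numeric(0)
  list(nll = -sum(log(pr)), grad = unname(c(g_alpha, g_beta)))
}

# BFGS fallback on the unconstrained log-increment parameterization.
fit_po_bfgs <- function(X, y, K, theta0, maxit, reltol) {
  n <- length(y)
  p <- ncol(X)
  ncut <- K - 1L
  unpack_alpha <- function(par) {
    if (ncut == 1L) par[1L] else cumsum(c(par[1L], exp(par[2:ncut])))
  }
  nll <- function(par) {
    alpha <- unpack_alpha(par)
    eta <- if (p) drop(X %*% par[ncut + seq_len(p)]) else numeric(n)
    pr <- stats::plogis(c(alpha, Inf)[y] - eta) -
      stats::plogis(c(-Inf, alpha)[y] - eta)
    -sum(log(pmax(pr, 1e-300)))
  }
  gr <- function(par) {
    alpha <- unpack_alpha(par)
    eta <- if (p) drop(X %*% par[ncut + seq_len(p)]) else numeric(n)
    hi <- c(alpha, Inf)[y] - eta
    lo <- c(-Inf, alpha)[y] - eta
    pr <- pmax(stats::plogis(hi) - stats::plogis(lo), 1e-300)
    d_hi <- ifelse(is.finite(hi), stats::dlogis(hi), 0) / pr
    d_lo <- ifelse(is.finite(lo), stats::dlogis(lo), 0) / pr
    g_beta <- if (p) drop(crossprod(X, d_hi - d_lo)) else numeric(0)
    galpha <- vapply(seq_len(ncut), function(j)
      -(sum(d_hi[y == j]) - sum(d_lo[y == j + 1L])), numeric(1))
    g_cut <- numeric(ncut)
    g_cut[1L] <- sum(galpha)
    if (ncut > 1L) {
      tails <- rev(cumsum(rev(galpha)))
      g_cut[2:ncut] <- exp(par[2:ncut]) * tails[2:ncut]
    }
    c(g_cut, g_beta)
  }
  a0 <- theta0[seq_len(ncut)]
  if (any(diff(a0) <= 0)) a0 <- sort(a0) + seq_len(ncut) * 1e-6
  par0 <- c(a0[1L], if (ncut > 1L) log(pmax(diff(a0), 1e-6)),
            theta0[ncut + seq_len(p)])
  opt <- stats::optim(par0, nll, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  alpha <- unpack_alpha(opt$par)
  list(theta = c(alpha, opt$par[ncut + seq_len(p)]))
}

#' Fit the transitional proportional-odds model
#'
#' Maximum-likelihood fit of the cumulative-logit model on long-format
#' rows, with cutpoints kept ordered through a log-increment
#' reparameterization and BFGS with analytic gradients.  Aliased columns
#' (rank deficiency after level dropping) are removed and recorded before
#' fitting.  Non-convergence never throws: the result carries
#' `converged = FALSE`.
#'
#' @param rows Long-format rows from [build_transitional_rows()].
#' @param include_treatment Include the treatment indicator (`beta_trt`)?
#' @param options List; recognised entries `maxit` (default 500), `gtol`
#'   (gradient sup-norm tolerance *per row*, default 1e-6), `start`
#'   (warm-start parameter vector from a previous fit's `$theta`).
#' @return Object of class `po_fit`: `coefficients` (a
#'   [coefficient_set()]), `log_likelihood`, `converged`, `separation`,
#'   `n_rows`, `dropped_levels`, `grad_sup`, plus internals for refits.
#' @export
#' @examples
#' pop <- make_synthetic_population(seed = 1)
#' trial <- simulate_trial(pop, n_total = 60, beta_trt = log(1.3), seed = 3)
#' fit <- fit_proportional_odds(build_transitional_rows(trial),
#'                              include_treatment = TRUE)
#' fit$coefficients$beta_trt
fit_proportional_odds <- function(rows, include_treatment = FALSE,
                                  options = list()) {
  maxit <- options$maxit %||% 500L
  gtol <- options$gtol %||% 1e-6
  des <- encode_design(rows, include_treatment = include_treatment)
  X <- des$X
  dropped <- des$dropped_levels

  if (ncol(X)) {
    dec <- qr(X)
    if (dec$rank < ncol(X)) {
      keep <- sort(dec$pivot[seq_len(dec$rank)])
      dropped$aliased <- colnames(X)[-keep]
      X <- X[, keep, drop = FALSE]
    }
  }

  K <- length(des$outcome_levels)
  fit <- fit_po_xy(X, des$y, K, start = options$start,
                   maxit = maxit, gtol = gtol)

  structure(
    list(coefficients = assemble_coefficients(fit, des),
         log_likelihood = fit$logLik,
         converged = fit$converged,
         separation = fit$separation,
         grad_sup = fit$grad_sup,
         n_rows = des$n,
         dropped_levels = dropped,
         outcome_levels = des$outcome_levels,
         theta = fit$theta,
         design_labels = colnames(X)),
    class = "po_fit")
}

assemble_coefficients <- function(fit, des) {
  beta <- fit$beta
  pick <- function(prefix) {
    if (!length(beta)) return(NULL)
    keep <- startsWith(names(beta), prefix)
    if (!any(keep)) return(NULL)
    stats::setNames(beta[keep], substring(names(beta)[keep], nchar(prefix) + 1L))
  }
  coefficient_set(
    cutpoints = fit$alpha,
    beta_lev = pick("lev:"),
    beta_base = pick("base:"),
    beta_auto = pick("auto:"),
    beta_trt = if ("trt" %in% names(beta)) beta[["trt"]] else 0,
    outcome_levels = des$outcome_levels)
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Transitional proportional-odds fit\n")
  cat(sprintf("  rows: %d   logLik: %.3f   converged: %s%s\n",
              x$n_rows, x$log_likelihood, x$converged,
              if (x$separation) "   [separation suspected]" else ""))
  if (length(x$design_labels) && "trt" %in% x$design_labels)
    cat(sprintf("  beta_trt: %.4f (OR %.3f)\n",
                x$coefficients$beta_trt, exp(x$coefficients$beta_trt)))
  dl <- x$dropped_levels
  ndrop <- sum(lengths(dl[c("lev", "y_base", "y_auto", "outcome")]))
  if (ndrop) cat("  unobserved levels dropped:", ndrop, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
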