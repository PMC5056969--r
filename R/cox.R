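# Cox proportional-hazards fitting by Newton-Raphson on the partial
# likelihood, with Efron (default) or Breslow handling of tied event times.

cox_loglik <- function(beta, time, event, X, ties) {
  n <- length(time)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]; e_s <- event[ord]; X_s <- X[ord, , drop = FALSE]
  w_s <- w[ord]; eta_s <- eta[ord]

  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    # add the whole tied-time block to the risk set
    j <- i
    while (j <= n && t_s[j] == t_s[i]) j <- j + 1L
    block <- i:(j - 1L)
    for (b in block) {
      S0 <- S0 + w_s[b]
      S1 <- S1 + w_s[b] * X_s[b, ]
      S2 <- S2 + w_s[b] * tcrossprod(X_s[b, ])
    }
    deaths <- block[e_s[block] == 1]
    d <- length(deaths)
    if (d > 0) {
      ll <- ll + sum(eta_s[deaths])
      grad <- grad + colSums(X_s[deaths, , drop = FALSE])
      if (ties == "efron" && d > 1) {
        S0d <- sum(w_s[deaths])
        S1d <- colSums(w_s[deaths] * X_s[deaths, , drop = FALSE])
        S2d <- matrix(0, p, p)
        for (b in deaths) S2d <- S2d + w_s[b] * tcrossprod(X_s[b, ])
        for (l in 0:(d - 1)) {
          f <- l / d
          phi0 <- S0 - f * S0d
          phi1 <- S1 - f * S1d
          phi2 <- S2 - f * S2d
          ll <- ll - log(phi0)
          grad <- grad - phi1 / phi0
          info <- info + phi2 / phi0 - tcrossprod(phi1 / phi0)
        }
      } else {
        ll <- ll - d * log(S0)
        grad <- grad - d * S1 / S0
        info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
      }
    }
    i <- j
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with step-halving;
#' Efron tie handling by default (Breslow optional). Wald confidence
#' intervals `exp(beta +/- z * se)` and a likelihood-ratio test against the
#' null model are reported. Monotone likelihood (separation) is detected by
#' coefficient divergence: the estimate is bounded (|beta| <= 15) and the
#' fit flagged non-converged, never silently returned.
#'
#' @param records Data frame with `sample_id`, `time`, `event` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A `cox_fit`: tibble-backed terms (`term`, `beta`, `se`, `hr`,
#'   `ci_lo`, `ci_hi`, `p`) in `$terms`, plus `loglik`, `loglik_null`,
#'   `lrt_p`, `n`, `n_events`, `converged`, `ties`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95, max_iter = 30L, tol = 1e-9) {
  ties <- match.arg(ties)
  check_survival(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) {
    rlang::abort(sprintf("Covariate(s) not in records: %s",
                         paste(miss, collapse = ", ")))
  }
  X <- as.matrix(records[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) rlang::abort("Covariates must be finite (no NA).")
  if (sum(records$event) < 1) rlang::abort("Need >= 1 event to fit.")
  vv <- apply(X, 2, var)
  if (any(vv == 0)) {
    rlang::abort(sprintf("Zero-variance covariate(s): %s",
                         paste(covariates[vv == 0], collapse = ", ")))
  }
  # collinearity check, naming an offending pair when present; the constant
  # column is included because additive shifts drop out of the partial
  # likelihood, so affine dependence is dependence
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    cm <- abs(cor(X))
    diag(cm) <- 0
    idx <- which(cm > 1 - 1e-10, arr.ind = TRUE)
    pair <- if (nrow(idx)) {
      paste(covariates[min(idx[1, ])], "and", covariates[max(idx[1, ])])
    } else "a linear combination of covariates"
    rlang::abort(sprintf("Collinear covariates: %s.", pair))
  }

  # center covariates for numerical stability; beta is invariant
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  time <- records$time
  event <- records$event
  p <- ncol(Xc)
  beta <- numeric(p)
  cur <- cox_loglik(beta, time, event, Xc, ties)
  ll_null <- cox_loglik(numeric(p), time, event, Xc, ties)$loglik
  converged <- FALSE
  bound_hit <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$information, cur$gradient),
                     error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: accept only likelihood-increasing steps
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      nxt <- cox_loglik(beta_new, time, event, Xc, ties)
      if (nxt$loglik >= cur$loglik - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (any(abs(beta_new) > 15)) {
      beta_new <- pmin(pmax(beta_new, -15), 15)
      nxt <- cox_loglik(beta_new, time, event, Xc, ties)
      bound_hit <- TRUE
    }
    delta_ll <- abs(nxt$loglik - cur$loglik)
    beta <- beta_new
    cur <- nxt
    if (delta_ll < tol && !bound_hit) {
      converged <- TRUE
      break
    }
    if (bound_hit && delta_ll < tol) break
  }
  if (bound_hit) {
    rlang::warn("Monotone partial likelihood suspected: estimate bounded at |beta| = 15; fit flagged non-converged.")
    converged <- FALSE
  }
  se <- sqrt(diag(tryCatch(solve(cur$information),
                           error = function(e) matrix(NA_real_, p, p))))
  z <- qnorm(1 - (1 - conf_level) / 2)
  terms <- tibble::tibble(
    term = covariates,
    beta = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    ci_lo = exp(unname(beta) - z * unname(se)),
    ci_hi = exp(unname(beta) + z * unname(se)),
    p = 2 * pnorm(-abs(unname(beta) / unname(se)))
  )
  lrt <- 2 * (cur$loglik - ll_null)
  structure(list(
    terms = terms,
    loglik = cur$loglik,
    loglik_null = ll_null,
    lrt_stat = lrt,
    lrt_p = pchisq(lrt, df = p, lower.tail = FALSE),
    n = nrow(records),
    n_events = sum(event),
    converged = converged,
    ties = ties,
    conf_level = conf_level
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n", x$n, x$n_events,
              x$ties, if (!x$converged) " [NOT CONVERGED]" else ""))
  print(as.data.frame(x$terms), digits = digits, row.names = FALSE)
  cat(sprintf("Likelihood ratio test p = %.3g\n", x$lrt_p))
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  dplyr::rename(x$terms, estimate = "beta", std.error = "se",
                conf.low = "ci_lo", conf.high = "ci_hi", p.value = "p")
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, logLik = x$loglik,
    logLik_null = x$loglik_null, lrt_stat = x$lrt_stat, lrt_p = x$lrt_p,
    converged = x$converged, ties = x$ties
  )
}
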