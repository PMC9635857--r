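# Maximum-likelihood HKA test.  Polymorphism counts S_i and divergence
# counts D_i at each locus are modeled as independent Poisson draws:
#   S_i ~ Poisson(kappa_i * theta_i * a(n_i)),   a(n) = sum_{1}^{n-1} 1/i
#   D_i ~ Poisson(theta_i * (T + 1))
# with kappa_i = k at the focal locus under the selection model and 1
# otherwise.  T is divergence time in units of 2N generations; the additive
# constant convention is absorbed by T, so inference about k does not
# depend on it.  The neutral model is the k = 1 restriction, making the
# likelihood-ratio test a 1-df chi-square.

#' Assemble per-locus HKA count data
#'
#' @param locus_id character vector of locus names.
#' @param S integer vector of segregating-site counts.
#' @param D integer vector of divergence counts (differences to a single
#'   outgroup sequence).
#' @param n integer vector of sample sizes (haplotypes).
#' @param role character vector, `"focal"` (at most one) or `"neutral"`.
#' @param L optional locus lengths (bookkeeping only).
#' @return data.frame of class `hka_data`.
#' @export
hka_data <- function(locus_id, S, D, n, role, L = NA_integer_) {
  check_that(length(locus_id) >= 2L, "HKA needs at least 2 loci")
  check_that(all(S >= 0) && all(D >= 0), "counts must be nonnegative")
  check_that(all(n >= 2), "sample sizes must be >= 2")
  check_that(all(role %in% c("focal", "neutral")),
             "role must be 'focal' or 'neutral'")
  check_that(sum(role == "focal") <= 1L, "at most one focal locus")
  out <- data.frame(
    locus_id = locus_id, S = as.integer(S), D = as.integer(D),
    n = as.integer(n), role = role, L = L, stringsAsFactors = FALSE
  )
  class(out) <- c("hka_data", "data.frame")
  out
}

hka_loglik <- function(log_theta, log_T, log_k, data, focal_idx) {
  theta <- exp(log_theta)
  T_ <- exp(log_T)
  kappa <- rep(1, nrow(data))
  if (!is.na(log_k) && length(focal_idx)) kappa[focal_idx] <- exp(log_k)
  a <- vapply(data$n, harmonic_a1, numeric(1))
  sum(stats::dpois(data$S, kappa * theta * a, log = TRUE)) +
    sum(stats::dpois(data$D, theta * (T_ + 1), log = TRUE))
}

# Profile MLE of theta given T (and k): each locus factorizes.
hka_profile_theta <- function(data, T_, k, focal_idx) {
  a <- vapply(data$n, harmonic_a1, numeric(1))
  kappa <- rep(1, nrow(data))
  if (length(focal_idx)) kappa[focal_idx] <- k
  (data$S + data$D) / (kappa * a + T_ + 1)
}

#' Fit the HKA Poisson model
#'
#' Maximizes the log-likelihood over per-locus theta > 0, divergence time
#' T > 0 (and the selection parameter k > 0 of the focal locus under the
#' selection model) by multi-start BFGS in log-parameter space.  The
#' selection fit is warm-started at the neutral optimum (with k = 1) so its
#' likelihood can never fall below the neutral one.  A locus with S = D = 0
#' drives its theta to the zero boundary and is flagged.
#'
#' @param data an `hka_data`.
#' @param model `"neutral"` or `"selection"` (the latter requires a focal
#'   locus).
#' @param n_starts number of deterministic optimizer starts.
#' @return list of class `hka_fit`: `model`, `theta_hat` (named), `T_hat`,
#'   `k_hat` (`NA` for neutral), `lnL`, `boundary_loci`, `convergence`.
#' @export
hka_fit <- function(data, model = c("neutral", "selection"), n_starts = 5L) {
  model <- match.arg(model)
  check_that(inherits(data, "hka_data") || all(
    c("locus_id", "S", "D", "n", "role") %in% names(data)
  ), "`data` must be an hka_data table")
  focal_idx <- which(data$role == "focal")
  if (model == "selection") {
    check_that(length(focal_idx) == 1L,
               "selection model requires exactly one focal locus")
  }
  zero <- data$S + data$D == 0L
  nloc <- nrow(data)
  has_k <- model == "selection"

  obj <- function(p) {
    lt <- p[seq_len(nloc)]
    lT <- p[nloc + 1L]
    lk <- if (has_k) p[nloc + 2L] else NA_real_
    ll <- hka_loglik(lt, lT, lk, data, focal_idx)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # deterministic start grid around the profile estimates
  T_starts <- c(1, 0.25, 4, 0.05, 20)[seq_len(n_starts)]
  base_T <- max(sum(data$D) / max(sum(pmax(data$S, 0.5)) /
                                    mean(vapply(data$n, harmonic_a1,
                                                numeric(1))), 1e-6), 0.1)
  starts <- lapply(T_starts, function(f) {
    T0 <- base_T * f
    th0 <- pmax(hka_profile_theta(data, T0, 1, focal_idx), 1e-8)
    c(log(th0), log(T0), if (has_k) 0)
  })
  if (has_k) {
    neut <- hka_fit(data, "neutral", n_starts = n_starts)
    starts <- c(
      list(c(log(pmax(neut$theta_hat, 1e-12)), log(neut$T_hat), 0)),
      starts
    )
  }

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  check_that(!is.null(best), "HKA optimization failed for all starts")
  theta_hat <- exp(best$par[seq_len(nloc)])
  theta_hat[zero] <- 0
  names(theta_hat) <- data$locus_id
  structure(
    list(
      model = model,
      theta_hat = theta_hat,
      T_hat = unname(exp(best$par[nloc + 1L])),
      k_hat = if (has_k) unname(exp(best$par[nloc + 2L])) else NA_real_,
      lnL = -best$value,
      boundary_loci = data$locus_id[zero],
      convergence = best$convergence
    ),
    class = "hka_fit"
  )
}

#' @export
print.hka_fit <- function(x, ...) {
  cat(sprintf("<hka_fit> %s model: lnL = %.4f, T = %.4g%s\n",
              x$model, x$lnL, x$T_hat,
              if (!is.na(x$k_hat)) sprintf(", k = %.4g", x$k_hat) else ""))
  invisible(x)
}

#' Likelihood-ratio HKA test
#'
#' Fits the neutral (k = 1) and selection models and compares them:
#' LRT = 2 (lnL_selection - lnL_neutral), clamped at zero, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param data an `hka_data` with exactly one focal locus.
#' @param n_starts optimizer starts per fit.
#' @return list of class `hka_test` with `lrt`, `p_value`, `neutral`,
#'   `selection` (the two `hka_fit` objects).
#' @export
hka_test <- function(data, n_starts = 5L) {
  neut <- hka_fit(data, "neutral", n_starts = n_starts)
  sel <- hka_fit(data, "selection", n_starts = n_starts)
  lrt <- max(2 * (sel$lnL - neut$lnL), 0)
  structure(
    list(
      lrt = lrt,
      p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
      neutral = neut, selection = sel
    ),
    class = "hka_test"
  )
}

#' @export
print.hka_test <- function(x, ...) {
  cat(sprintf("<hka_test> LRT = %.4f, p = %.4g (k_hat = %.4g)\n",
              x$lrt, x$p_value, x$selection$k_hat))
  invisible(x)
}
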