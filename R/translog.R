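# Translog cost-function estimation of factor shares.
#
# ln C = b0 + sum_i b_i ln p_i + 1/2 sum_ij g_ij ln p_i ln p_j + d_y ln y
# with symmetry (g_ij = g_ji) and linear homogeneity in prices. Homogeneity
# is imposed by normalizing cost and the first three factor prices by the
# indirect-cost price (the numeraire), leaving three free first-order terms
# and a 3x3 symmetric second-order block. Differentiating in log prices
# (Shephard's lemma) gives the cost share of each factor:
#   s_i = b_i + sum_j g_ij ln(p_j / p_4),  s_4 = 1 - s_1 - s_2 - s_3.

translog_design <- function(df, price_output_interaction = FALSE) {
  lp <- log(as.matrix(df[paste0("price_", FACTOR_NAMES[1:3])]) /
            df$price_indirect)
  colnames(lp) <- FACTOR_NAMES[1:3]
  X <- lp
  colnames(X) <- paste0("b_", FACTOR_NAMES[1:3])
  for (i in 1:3) {
    for (j in i:3) {
      col <- if (i == j) 0.5 * lp[, i]^2 else lp[, i] * lp[, j]
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("g_", i, j)
    }
  }
  lny <- log(df$output_volume)
  X <- cbind(X, d_y = lny)
  if (price_output_interaction) {
    for (i in 1:3) {
      X <- cbind(X, lp[, i] * lny)
      colnames(X)[ncol(X)] <- paste0("py_", i)
    }
  }
  list(X = X, lp = lp, lny = lny, y = log(df$total_cost / df$price_indirect))
}

#' Fit a translog cost function to facility cost records
#'
#' Least-squares fit of the normalized translog cost function (see Details)
#' for one facility level, with a heteroskedasticity-robust (Huber/White
#' sandwich, HC1) coefficient covariance.
#'
#' @details The regression is of `ln(total_cost / price_indirect)` on the
#' three log normalized prices, their symmetric second-order products, and
#' `ln(output_volume)`. Normalizing by the indirect-cost price imposes linear
#' homogeneity in prices; symmetry holds by construction of the design.
#' Factor shares follow by differentiation, see [derive_shares()].
#'
#' @param records facility cost table (see [read_facilities()]).
#' @param level `"hospital"` or `"health_centre"`; rows of other levels are
#'   dropped.
#' @param price_output_interaction include price-by-output interaction terms
#'   (off by default; the homothetic specification).
#' @return object of class `translog_fit` with elements `coefficients`,
#'   `vcov` (robust), `beta`, `gamma` (3x3 symmetric), `delta_y`,
#'   `adj_r2`, `n_obs`, `eval_point` (mean log normalized prices), `level`.
#' @export
fit_translog <- function(records, level = c("hospital", "health_centre"),
                         price_output_interaction = FALSE) {
  level <- match.arg(level)
  df <- validate_facilities(records)
  df <- df[df$level == level, , drop = FALSE]
  d <- translog_design(df, price_output_interaction)
  X <- cbind(`(Intercept)` = 1, d$X)
  k <- ncol(X)
  if (nrow(X) < k + 5L) {
    ck_domain_error(sprintf(
      "need at least %d records at level '%s' (%d regressors + 5); got %d",
      k + 5L, level, k, nrow(X)))
  }
  qx <- qr(X)
  if (qx$rank < k) {
    ck_domain_error("singular design matrix: facility prices/output do not identify the translog coefficients")
  }
  coefs <- qr.coef(qx, d$y)
  resid <- d$y - drop(X %*% coefs)
  V <- sandwich_covariance(X, resid)
  n <- nrow(X)
  ss_res <- sum(resid^2)
  ss_tot <- sum((d$y - mean(d$y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)

  gamma <- matrix(0, 3, 3, dimnames = list(FACTOR_NAMES[1:3], FACTOR_NAMES[1:3]))
  for (i in 1:3) for (j in i:3) {
    gamma[i, j] <- gamma[j, i] <- coefs[[paste0("g_", i, j)]]
  }
  rho <- if (price_output_interaction) {
    stats::setNames(coefs[paste0("py_", 1:3)], FACTOR_NAMES[1:3])
  } else {
    stats::setNames(numeric(3), FACTOR_NAMES[1:3])
  }
  structure(list(
    coefficients = coefs, vcov = V,
    beta = stats::setNames(coefs[paste0("b_", FACTOR_NAMES[1:3])],
                           FACTOR_NAMES[1:3]),
    gamma = gamma, rho = rho, delta_y = coefs[["d_y"]],
    price_output_interaction = price_output_interaction,
    adj_r2 = adj_r2, n_obs = n,
    eval_point = list(lp = colMeans(d$lp), lny = mean(d$lny)),
    level = level, design = X, residuals = resid),
    class = "translog_fit")
}

#' @export
print.translog_fit <- function(x, ...) {
  cat(sprintf("Translog cost-function fit (%s): n = %d, adjusted R^2 = %.4f\n",
              x$level, x$n_obs, x$adj_r2))
  print(derive_shares(x))
  invisible(x)
}

#' Heteroskedasticity-robust (Huber/White sandwich, HC1) covariance
#'
#' `(X'X)^-1 X' diag(e^2) X (X'X)^-1` scaled by `n / (n - k)`, for residuals
#' `e` from an ordinary least-squares fit with design matrix `X` (including
#' the intercept column).
#'
#' @param X design matrix (n x k, full column rank).
#' @param residuals OLS residual vector of length n.
#' @return k x k covariance matrix.
#' @export
sandwich_covariance <- function(X, residuals) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  if (length(residuals) != n) {
    ck_domain_error("residuals length must match nrow(X)")
  }
  if (qr(X)$rank < k) {
    ck_domain_error("rank-deficient design matrix")
  }
  bread <- solve(crossprod(X))
  meat <- crossprod(X * residuals^2, X)   # sum_i e_i^2 x_i x_i'
  n / (n - k) * bread %*% meat %*% bread
}

#' Derive factor shares from a fitted translog cost function
#'
#' By Shephard's lemma the cost share of factor i is the derivative of log
#' cost with respect to log price i: `s_i = b_i + sum_j g_ij ln p~_j` at the
#' evaluation point (the sample mean of log normalized prices by default).
#' The numeraire share is `1 - s_1 - s_2 - s_3`, so the four shares sum to 1
#' exactly by construction. Standard errors are delta-method linear
#' combinations of the robust coefficient covariance.
#'
#' @param fit a `translog_fit` (or a share-system fit).
#' @param eval_point log normalized prices (length-3 numeric) at which to
#'   evaluate the shares; defaults to the fit's sample mean.
#' @return a [factor_shares()] vector with an `se` attribute (robust
#'   delta-method standard errors; the numeraire's SE follows from the sum
#'   constraint).
#' @export
derive_shares <- function(fit, eval_point = NULL) {
  if (is.null(eval_point)) eval_point <- fit$eval_point$lp
  if (length(eval_point) != 3L) {
    ck_domain_error("eval_point must have length 3 (log normalized prices)")
  }
  s3 <- as.numeric(fit$beta + fit$gamma %*% eval_point +
                   fit$rho * fit$eval_point$lny)
  s <- c(s3, 1 - sum(s3))
  names(s) <- FACTOR_NAMES

  se <- rep(NA_real_, 4L)
  if (!is.null(fit$vcov)) {
    cn <- colnames(fit$vcov)
    if (is.null(cn)) cn <- names(fit$coefficients)
    a <- matrix(0, nrow = length(fit$coefficients), ncol = 3L,
                dimnames = list(names(fit$coefficients), NULL))
    for (i in 1:3) {
      a[paste0("b_", FACTOR_NAMES[i]), i] <- 1
      for (j in 1:3) {
        nm <- paste0("g_", min(i, j), max(i, j))
        a[nm, i] <- a[nm, i] + eval_point[j]
      }
      if (isTRUE(fit$price_output_interaction)) {
        a[paste0("py_", i), i] <- fit$eval_point$lny
      }
    }
    a <- cbind(a, -rowSums(a))  # numeraire share: 1 - sum of the others
    se <- sqrt(diag(t(a) %*% fit$vcov %*% a))
  }
  out <- factor_shares(s[1L], s[2L], s[3L], s[4L], level = fit$level)
  attr(out, "se") <- stats::setNames(se, FACTOR_NAMES)
  attr(out, "eval_point") <- eval_point
  out
}

#' Fit the factor-share equation system directly
#'
#' Alternative estimator for sensitivity analysis: regresses the observed
#' expenditure shares (which requires the optional `exp_*` columns in the
#' facility table) of the three non-numeraire factors on the log normalized
#' prices, equation by equation (with identical regressors across equations,
#' SUR reduces to per-equation OLS). Symmetry is not imposed. The numeraire
#' equation is dropped and recovered from the adding-up constraint.
#'
#' @inheritParams fit_translog
#' @return object of class `share_system_fit`, usable with [derive_shares()]
#'   (standard errors are not reported for this estimator).
#' @export
fit_share_system <- function(records, level = c("hospital", "health_centre")) {
  level <- match.arg(level)
  df <- validate_facilities(records)
  exp_cols <- paste0("exp_", FACTOR_NAMES)
  if (!all(exp_cols %in% names(df))) {
    ck_validation_error(
      "share-system estimation requires per-factor expenditure columns (exp_personnel, exp_consumables, exp_other_direct, exp_indirect)",
      "facilities")
  }
  df <- df[df$level == level, , drop = FALSE]
  d <- translog_design(df)
  lp <- d$lp
  if (nrow(lp) < 9L) {
    ck_domain_error("need at least 9 records for the share system")
  }
  beta <- stats::setNames(numeric(3), FACTOR_NAMES[1:3])
  gamma <- matrix(0, 3, 3, dimnames = list(FACTOR_NAMES[1:3], FACTOR_NAMES[1:3]))
  for (i in 1:3) {
    share_i <- df[[exp_cols[i]]] / df$total_cost
    cf <- stats::lm.fit(cbind(1, lp), share_i)$coefficients
    beta[i] <- cf[1L]
    gamma[i, ] <- cf[-1L]
  }
  structure(list(beta = beta, gamma = gamma,
                 rho = stats::setNames(numeric(3), FACTOR_NAMES[1:3]),
                 vcov = NULL, n_obs = nrow(lp),
                 eval_point = list(lp = colMeans(lp), lny = mean(d$lny)),
                 level = level),
            class = "share_system_fit")
}

#' Factor-share report table
#'
#' Percentages (one decimal) of the total unit cost attributable to each of
#' the four factors, by facility level, with robust standard errors and
#' sample sizes where a fit is supplied. Called without arguments it reports
#' the packaged default shares (see [default_factor_shares()]).
#'
#' @param fits `NULL` for the packaged defaults, or a named list with
#'   elements `hospital` and `health_centre`, each a `translog_fit` (or
#'   anything [derive_shares()] accepts).
#' @param renormalize rescale each row to sum to exactly 100%.
#' @return data.frame with columns `level`, the four factor percentages,
#'   `se_*` (percentage points) and `n_obs`.
#' @export
shares_report <- function(fits = NULL, renormalize = FALSE) {
  levels <- c("hospital", "health_centre")
  rows <- lapply(levels, function(lv) {
    if (is.null(fits)) {
      s <- default_factor_shares(lv, renormalize = renormalize)
      se <- rep(NA_real_, 4L)
      n <- NA_integer_
    } else {
      if (is.null(fits[[lv]])) {
        ck_validation_error(sprintf("missing fit for level '%s'", lv), "fits")
      }
      s <- derive_shares(fits[[lv]])
      if (renormalize) s[] <- s / sum(s)
      se <- attr(s, "se")
      n <- fits[[lv]]$n_obs
    }
    pct <- round(100 * unclass(s), 1)
    data.frame(level = lv,
               personnel = pct[[1L]], consumables = pct[[2L]],
               other_direct = pct[[3L]], indirect = pct[[4L]],
               se_personnel = round(100 * se[1L], 2),
               se_consumables = round(100 * se[2L], 2),
               se_other_direct = round(100 * se[3L], 2),
               se_indirect = round(100 * se[4L], 2),
               n_obs = n)
  })
  do.call(rbind, rows)
}
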