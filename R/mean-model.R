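#' Specify the conditional mean model E(Y | X, Z) = g(X, Z; beta)
#'
#' Builds the regression model whose coefficient vector beta is the target of
#' estimation. Two mean functions are supported: `linear`,
#' g = beta0 + beta_X . X + beta_Z . Z, and `logistic`,
#' g = expit(beta0 + beta_X . X + beta_Z . Z). The coefficient ordering is
#' fixed as (intercept, X block, Z block) and every reported estimate follows
#' it.
#'
#' The index function d(X, Z) entering the estimating equation defaults to the
#' beta-gradient of the mean (a constant working variance, the OLS-type
#' choice). A working-variance function `var_fun(x_row, z_row)` may be
#' supplied; index rows are then rescaled by its reciprocal, giving the
#' efficient d under heteroscedasticity.
#'
#' @param kind `"linear"` or `"logistic"`.
#' @param p Number of partially observed covariates (columns of X), >= 1.
#' @param q Number of fully observed covariates (columns of Z), >= 0.
#' @param var_fun Optional working-variance function taking matrices
#'   (`x`, `z`) and returning a positive vector of Var(Y | X, Z) values.
#' @return An object of class `acc_mean_model` with elements `kind`, `p`,
#'   `q`, `beta_dim = 1 + p + q`, and vectorised functions `mean(x, z,
#'   beta)`, `gradient(x, z, beta)` (n x beta_dim) and `index(x, z, beta)`.
#' @examples
#' m <- mean_model("linear", p = 1, q = 1)
#' m$beta_dim
#' m$mean(matrix(2), matrix(3), c(0, 0.2, 0.2)) # 1.0
#' @export
mean_model <- function(kind = c("linear", "logistic"), p, q, var_fun = NULL) {
  kind <- match.arg(kind)
  stopifnot(p >= 1, q >= 0)
  beta_dim <- 1L + p + q

  linpred <- function(x, z, beta) {
    check_beta(beta, beta_dim)
    drop(beta[1] + x %*% beta[2:(1 + p)] +
           if (q > 0) z %*% beta[(2 + p):beta_dim] else 0)
  }
  mean_fun <- switch(kind,
    linear = function(x, z, beta) linpred(x, z, beta),
    logistic = function(x, z, beta) expit(linpred(x, z, beta))
  )
  gradient <- switch(kind,
    linear = function(x, z, beta) {
      check_beta(beta, beta_dim)
      cbind(1, x, z, deparse.level = 0)
    },
    logistic = function(x, z, beta) {
      mu <- expit(linpred(x, z, beta))
      (mu * (1 - mu)) * cbind(1, x, z, deparse.level = 0)
    }
  )
  index <- function(x, z, beta) {
    g <- gradient(x, z, beta)
    if (!is.null(var_fun)) g <- g / var_fun(x, z)
    g
  }
  structure(
    list(kind = kind, p = p, q = q, beta_dim = beta_dim,
         mean = mean_fun, gradient = gradient, index = index,
         var_fun = var_fun),
    class = "acc_mean_model"
  )
}

expit <- function(u) stats::plogis(u)

check_beta <- function(beta, beta_dim) {
  if (length(beta) != beta_dim) {
    stop("beta has length ", length(beta), " but the model has beta_dim = ",
         beta_dim)
  }
  invisible(beta)
}

#' @export
print.acc_mean_model <- function(x, ...) {
  cat("<acc_mean_model>", x$kind, "mean, p =", x$p, ", q =", x$q,
      ", beta_dim =", x$beta_dim, "\n")
  invisible(x)
}

#' Residuals eps(beta) = Y - g(X, Z; beta)
#'
#' Residuals are defined for complete cases only; for subjects with the X
#' block missing the entry is the explicit undefined marker `NA` (it
#' propagates through any arithmetic that erroneously touches it).
#'
#' @param model An [mean_model()] object.
#' @param data An [acc_data()] object.
#' @param beta Coefficient vector of length `model$beta_dim`.
#' @return Numeric vector of length n; `NA` where `r = 0`.
#' @export
acc_residuals <- function(model, data, beta) {
  check_beta(beta, model$beta_dim)
  eps <- rep(NA_real_, data$n)
  cc <- cc_idx(data)
  eps[cc] <- data$y[cc] -
    model$mean(data$x[cc, , drop = FALSE], data$z[cc, , drop = FALSE], beta)
  eps
}

#' Index matrix d(X_i, Z_i) for the estimating equation
#'
#' Row i is the index function evaluated at subject i's covariates; rows for
#' subjects with X missing are the explicit undefined marker `NA`.
#'
#' @inheritParams acc_residuals
#' @return n x beta_dim matrix; `NA` rows where `r = 0`.
#' @export
index_matrix <- function(model, data, beta) {
  check_beta(beta, model$beta_dim)
  d <- matrix(NA_real_, data$n, model$beta_dim)
  cc <- cc_idx(data)
  d[cc, ] <- model$index(data$x[cc, , drop = FALSE],
                         data$z[cc, , drop = FALSE], beta)
  d
}
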