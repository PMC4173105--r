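#' @title Augmentation functions phi(Y, Z, beta)
#'
#' @description An augmentation function adds, to the complete-case
#' estimating function, a term `(R - pi(Y,Z)) phi(Y,Z,beta)` that has mean
#' zero whenever the observation model is correct, and so recovers
#' information from incomplete cases without affecting consistency. The
#' variance-minimising choice for a given index function d is
#' `phi_opt(Y,Z,beta) = -E[d(X,Z) eps(beta) | Y, Z, R = 1]`, which this
#' module estimates parametrically (working model + Monte-Carlo
#' integration) or non-parametrically (Nadaraya-Watson kernel regression).
#'
#' @name acc_phi
NULL

new_phi <- function(label, eval, meta = list(), affine = FALSE) {
  structure(list(label = label, eval = eval, meta = meta, affine = affine),
            class = "acc_phi")
}

#' @export
print.acc_phi <- function(x, ...) {
  cat("<acc_phi>", x$label, "\n")
  invisible(x)
}

# run code with the RNG temporarily seeded, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Zero augmentation: plain complete-case analysis
#'
#' With phi = 0 the augmented estimating equation reduces to the
#' complete-case one, so [fit_acc()] with this choice reproduces
#' [fit_cca()] exactly.
#'
#' @param beta_dim Coefficient dimension.
#' @return An `acc_phi` whose evaluator returns an all-zero n x beta_dim
#'   matrix for any beta.
#' @export
phi_zero <- function(beta_dim) {
  stopifnot(beta_dim >= 1)
  new_phi("zero",
          function(data, beta) matrix(0, data$n, beta_dim),
          affine = TRUE)
}

#' Fit a normal linear working model for X given (Y, Z) in the complete cases
#'
#' Each X component is regressed on a basis of the fully observed variables
#' among complete cases, with maximum-likelihood (denominator n_CC) residual
#' variance. Mis-specification of this model costs efficiency of the
#' resulting ACC estimator but never its consistency.
#'
#' @param data An [acc_data()] object.
#' @param basis Character vector of basis terms over (Y, Z), same syntax as
#'   [missingness_design()]; default intercept + Y + all Z columns.
#' @return An object of class `acc_working_model`: `coef` (k x p), `sigma2`
#'   (length p, ML), `terms`, `n_cc`, and `predict(data)` returning the
#'   n x p matrix of conditional means for every subject.
#' @export
fit_working_model <- function(data, basis = NULL) {
  if (is.null(basis)) basis <- c("1", "Y", colnames(data$z))
  des <- missingness_design(basis)   # same (Y, Z) term syntax
  cc <- cc_idx(data)
  if (length(cc) < length(basis)) {
    stop("need at least ", length(basis), " complete cases to fit the ",
         length(basis), "-term working model")
  }
  b_cc <- des$build(data)[cc, , drop = FALSE]
  if (qr(b_cc)$rank < ncol(b_cc)) {
    stop("singular working-model basis among complete cases")
  }
  x_cc <- data$x[cc, , drop = FALSE]
  fit <- stats::lm.fit(b_cc, x_cc)
  coef <- matrix(fit$coefficients, ncol = data$p,
                 dimnames = list(basis, colnames(data$x)))
  res <- x_cc - b_cc %*% coef
  sigma2 <- colSums(res^2) / length(cc)
  if (any(sigma2 < 1e-12)) {
    stop("degenerate working model: residual variance below 1e-12 for X ",
         "component(s) ", paste(which(sigma2 < 1e-12), collapse = ", "))
  }
  structure(
    list(coef = coef, sigma2 = sigma2, terms = basis, n_cc = length(cc),
         predict = function(data) des$build(data) %*% coef),
    class = "acc_working_model"
  )
}

#' @export
print.acc_working_model <- function(x, ...) {
  cat("<acc_working_model> normal linear X | Y,Z,R=1 on basis:",
      paste(x$terms, collapse = ", "), "; n_CC =", x$n_cc, "\n")
  invisible(x)
}

#' Working-model augmentation via Monte-Carlo integration
#'
#' Estimates the optimal augmentation
#' `-E[d(X,Z) eps(beta) | Y, Z, R = 1]` by drawing, for each subject, `m`
#' improper imputations X* from the fitted working model and averaging
#' `-d(X*, Z) (Y - g(X*, Z; beta))` over them. The draws are a
#' deterministic function of `seed` and the subject index, hence frozen
#' across beta evaluations: the estimating equation stays smooth in beta
#' during root finding.
#'
#' @param model An [mean_model()].
#' @param wm An [fit_working_model()] fit (or any object with `predict` and
#'   `sigma2`).
#' @param m Number of Monte-Carlo draws per subject (default 10).
#' @param seed Integer seed for the frozen draws.
#' @return An `acc_phi`. Its evaluator attaches an `"mc_se"` attribute: the
#'   per-entry Monte-Carlo standard error of the m-draw average.
#' @export
phi_working_model <- function(model, wm, m = 10L, seed = 1L) {
  stopifnot(m >= 1)
  eval_fun <- function(data, beta) {
    mu <- wm$predict(data)                       # n x p conditional means
    sdv <- sqrt(wm$sigma2)
    dd <- model$beta_dim
    acc <- matrix(0, data$n, dd)
    acc2 <- matrix(0, data$n, dd)
    with_seed(seed, {
      noise <- array(stats::rnorm(data$n * m * data$p), c(data$n, m, data$p))
    })
    for (j in seq_len(m)) {
      nj <- matrix(noise[, j, ], nrow = data$n, ncol = data$p)
      xs <- mu + nj * matrix(sdv, data$n, data$p, byrow = TRUE)
      dj <- model$index(xs, data$z, beta)
      val <- -dj * (data$y - model$mean(xs, data$z, beta))
      acc <- acc + val
      acc2 <- acc2 + val^2
    }
    phi <- acc / m
    mc_se <- if (m > 1) sqrt(pmax(acc2 / m - phi^2, 0) / (m - 1)) else
      matrix(NA_real_, data$n, dd)
    attr(phi, "mc_se") <- mc_se
    phi
  }
  new_phi(paste0("working_model(m=", m, ")"), eval_fun,
          meta = list(wm = wm, m = m, seed = seed),
          affine = model$kind == "linear" && is.null(model$var_fun))
}

#' Rule-of-thumb bandwidths for kernel estimation of the augmentation
#'
#' For each conditioning variable (Y first, then every Z column) the
#' bandwidth is the complete-case sample standard deviation times
#' `n_CC^(-1/7)`, optionally rescaled. The -1/7 exponent satisfies the
#' undersmoothing conditions for the kernel ACC estimator with two
#' continuous conditioning variables.
#'
#' @param data An [acc_data()] object with at least 2 complete cases.
#' @param scale Multiplier applied to every bandwidth.
#' @param exponent Bandwidth exponent (default -1/7).
#' @return An object of class `acc_kernel_spec`: `h` (named vector over
#'   conditioning variables), `n_cc`.
#' @examples
#' # SD 2 and 128 complete cases give h = 2 * 128^(-1/7) = 1
#' @export
default_bandwidths <- function(data, scale = 1, exponent = -1/7) {
  cc <- cc_idx(data)
  if (length(cc) < 2) stop("need at least 2 complete cases for bandwidths")
  cond <- cbind(Y = data$y, data$z)[cc, , drop = FALSE]
  sds <- apply(cond, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero standard deviation of conditioning variable(s) ",
         paste(colnames(cond)[sds == 0], collapse = ", "))
  }
  h <- scale * sds * length(cc)^exponent
  structure(list(h = h, n_cc = length(cc)), class = "acc_kernel_spec")
}

#' Nadaraya-Watson kernel regression with a product normal kernel
#'
#' Kernel-weighted local average of `train_values` at each query row, with
#' independent standard-normal kernels per coordinate and per-coordinate
#' bandwidths.
#'
#' @param query_points Numeric matrix (m x r) of evaluation points.
#' @param train_points Numeric matrix (t x r) of training covariates.
#' @param train_values Numeric matrix (t x d) of training responses.
#' @param spec An `acc_kernel_spec` (only `h` is used).
#' @return m x d matrix of estimates. If every kernel weight underflows to
#'   zero at some query, an error names that query row rather than silently
#'   returning 0.
#' @export
nadaraya_watson <- function(query_points, train_points, train_values, spec) {
  q <- as.matrix(query_points); t_ <- as.matrix(train_points)
  v <- as.matrix(train_values)
  stopifnot(nrow(t_) >= 1, ncol(q) == ncol(t_), nrow(v) == nrow(t_),
            length(spec$h) == ncol(t_), all(spec$h > 0))
  w <- matrix(1, nrow(t_), nrow(q))
  for (k in seq_len(ncol(t_))) {
    w <- w * stats::dnorm(outer(t_[, k], q[, k], `-`) / spec$h[k])
  }
  denom <- colSums(w)
  if (any(denom == 0)) {
    stop("all kernel weights underflow to zero at query row(s) ",
         paste(which(denom == 0), collapse = ", "),
         "; increase the bandwidths")
  }
  crossprod(w, v) / denom
}

#' Kernel augmentation frozen at the complete-case estimate
#'
#' Nadaraya-Watson regression, over the complete cases, of the vector
#' `-d(X, Z) eps(beta_CCA)` on the fully observed (Y, Z), evaluated at every
#' subject. The augmentation is frozen at the complete-case estimate and is
#' beta-independent thereafter, avoiding re-estimation inside root finding;
#' the resulting estimator has the same asymptotic distribution as the one
#' using the true optimal augmentation.
#'
#' @inheritParams phi_working_model
#' @param data The dataset supplying the complete-case training sample.
#' @param beta_cca Complete-case estimate at which the augmentation is frozen.
#' @param spec An `acc_kernel_spec` (see [default_bandwidths()]).
#' @return A beta-independent `acc_phi`.
#' @export
phi_kernel_direct <- function(model, data, beta_cca, spec) {
  check_beta(beta_cca, model$beta_dim)
  cc <- cc_idx(data)
  train <- cbind(data$y, data$z)[cc, , drop = FALSE]
  d_cc <- model$index(data$x[cc, , drop = FALSE],
                      data$z[cc, , drop = FALSE], beta_cca)
  eps_cc <- data$y[cc] - model$mean(data$x[cc, , drop = FALSE],
                                    data$z[cc, , drop = FALSE], beta_cca)
  vals <- -d_cc * eps_cc
  # beta-independent: cache the kernel regression for repeated evaluation
  # at the same query set during root finding
  cache <- new.env(parent = emptyenv())
  new_phi("kernel_direct", function(eval_data, beta) {
    if (!identical(cache$y, eval_data$y)) {
      cache$y <- eval_data$y
      cache$fit <- nadaraya_watson(cbind(eval_data$y, eval_data$z),
                                   train, vals, spec)
    }
    cache$fit
  }, meta = list(h = spec$h), affine = TRUE)
}

# shared assembly of phi from conditional moments of a single X
# m1 = E(X|Y,Z,R=1), m2 = E(X^2|Y,Z,R=1); linear mean, homoscedastic d
phi_from_moments <- function(m1, m2, y, z, beta) {
  q <- ncol(z)
  b0 <- beta[1]; bx <- beta[2]
  bz <- if (q > 0) beta[3:(2 + q)] else numeric(0)
  zb <- if (q > 0) drop(z %*% bz) else 0
  e_full <- y - b0 - bx * m1 - zb      # E[eps | Y,Z,R=1]
  comp1 <- -e_full
  compx <- -(m1 * (y - b0 - zb) - bx * m2)
  out <- cbind(comp1, compx, if (q > 0) z * comp1, deparse.level = 0)
  colnames(out) <- NULL
  out
}

#' Kernel augmentation from conditional moments of X (linear mean, p = 1)
#'
#' Under a linear conditional mean the optimal augmentation depends only on
#' `E(X | Y, Z, R = 1)` and `E(X^2 | Y, Z, R = 1)`. Both moments are
#' estimated by Nadaraya-Watson regression over the complete cases and the
#' augmentation is assembled in closed form, so it remains a smooth
#' (affine) function of beta.
#'
#' @inheritParams phi_kernel_direct
#' @return An `acc_phi` with metadata `m1`, `m2` (estimated moments).
#' @export
phi_kernel_moments <- function(model, data, spec) {
  if (model$kind != "linear" || model$p != 1) {
    stop("the moment-based kernel augmentation requires a linear mean model ",
         "with a single X column")
  }
  cc <- cc_idx(data)
  train <- cbind(data$y, data$z)[cc, , drop = FALSE]
  x_cc <- data$x[cc, 1]
  mom <- nadaraya_watson(cbind(data$y, data$z), train,
                         cbind(x_cc, x_cc^2), spec)
  m1 <- mom[, 1]; m2 <- mom[, 2]
  new_phi("kernel_moments", function(eval_data, beta) {
    phi_from_moments(m1, m2, eval_data$y, eval_data$z, beta)
  }, meta = list(h = spec$h, m1 = m1, m2 = m2), affine = TRUE)
}
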