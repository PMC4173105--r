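#' Configuration of the synthetic-data generator
#'
#' The generator emulates a study in which the observation indicator R is
#' drawn first and the scalar covariates (X, Z) are drawn from a bivariate
#' normal whose mean depends on R but whose covariance does not; the outcome
#' is then generated from the linear conditional mean model given (X, Z)
#' only, so that R is independent of Y given (X, Z) by construction. The
#' common covariance across the two R groups makes both R | X, Z and
#' R | Y, Z exactly logistic with linear covariates.
#'
#' The residual variance is derived from the target coefficient of
#' determination: `sigma_eps^2 = Var(beta_X X + beta_Z Z) (1 - R2) / R2`,
#' with the variance taken under the two-group mixture marginal of (X, Z),
#' so the population R-squared equals `r_squared` exactly. The default
#' configuration (half the subjects observed, group mean shift
#' (1, 0.5) in (X, Z), identity covariance, coefficients (0, 0.2, 0.2),
#' R-squared 0.1) gives `sigma_eps^2 = 0.9225` and an MNAR-X mechanism:
#' missingness depends on X itself.
#'
#' @param n Sample size per dataset.
#' @param p_r Marginal observation probability P(R = 1).
#' @param beta_true True coefficients (intercept, X, Z).
#' @param mu0,mu1 Mean vectors of (X, Z) given R = 0 / R = 1.
#' @param sigma_xz Common 2 x 2 covariance of (X, Z) given R.
#' @param r_squared Target population coefficient of determination of
#'   Y on (X, Z).
#' @return An object of class `acc_generator_config`.
#' @export
generator_config <- function(n = 1000, p_r = 0.5,
                             beta_true = c(0, 0.2, 0.2),
                             mu0 = c(-0.5, -0.25), mu1 = c(0.5, 0.25),
                             sigma_xz = diag(2), r_squared = 0.1) {
  stopifnot(n >= 1, p_r > 0, p_r < 1, length(beta_true) == 3,
            length(mu0) == 2, length(mu1) == 2,
            r_squared > 0, r_squared < 1)
  sigma_xz <- as.matrix(sigma_xz)
  if (!isTRUE(all.equal(sigma_xz, t(sigma_xz))) ||
      any(eigen(sigma_xz, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("sigma_xz must be symmetric positive definite")
  }
  b <- beta_true[2:3]
  delta <- mu1 - mu0
  v_mix <- sigma_xz + p_r * (1 - p_r) * tcrossprod(delta)
  var_lin <- drop(t(b) %*% v_mix %*% b)
  sigma_eps2 <- var_lin * (1 - r_squared) / r_squared
  structure(
    list(n = n, p_r = p_r, beta_true = beta_true, mu0 = mu0, mu1 = mu1,
         sigma_xz = sigma_xz, r_squared = r_squared,
         sigma_eps2 = sigma_eps2),
    class = "acc_generator_config"
  )
}

#' @export
print.acc_generator_config <- function(x, ...) {
  cat("<acc_generator_config> n =", x$n, ", P(R=1) =", x$p_r,
      ", beta =", paste(x$beta_true, collapse = ", "),
      ", sigma_eps^2 =", format(x$sigma_eps2, digits = 6), "\n")
  invisible(x)
}

#' Draw one synthetic dataset
#'
#' @param config An [generator_config()].
#' @param seed Integer seed.
#' @return An [acc_data()] with columns Y, X (masked where R = 0), Z.
#' @export
generate_dataset <- function(config, seed) {
  cf <- config
  with_seed(seed, {
    r <- stats::rbinom(cf$n, 1, cf$p_r)
    e <- matrix(stats::rnorm(2 * cf$n), cf$n, 2) %*% chol(cf$sigma_xz)
    mu <- t(vapply(r, function(ri) if (ri == 1) cf$mu1 else cf$mu0,
                   numeric(2)))
    xz <- mu + e
    y <- cf$beta_true[1] + cf$beta_true[2] * xz[, 1] +
      cf$beta_true[3] * xz[, 2] +
      stats::rnorm(cf$n, sd = sqrt(cf$sigma_eps2))
    df <- data.frame(Y = y, X = ifelse(r == 1, xz[, 1], NA_real_),
                     Z = xz[, 2])
    out <- acc_data(df, outcome = "Y", x_cols = "X", z_cols = "Z")
    # unmasked X, for mechanism diagnostics on synthetic data only
    attr(out, "x_full") <- xz[, 1]
    out
  })
}

# moments of (Y, Z) given R = r implied by the generator
yz_given_r <- function(cf, group) {
  mu <- if (group == 1) cf$mu1 else cf$mu0
  b <- cf$beta_true[2:3]
  m <- c(cf$beta_true[1] + sum(b * mu), mu[2])
  sb <- drop(cf$sigma_xz %*% b)
  s <- matrix(c(sum(b * sb) + cf$sigma_eps2, sb[2],
                sb[2], cf$sigma_xz[2, 2]), 2, 2)
  list(mean = m, cov = s)
}

#' Closed-form coefficients of logit P(R = 1 | Y, Z)
#'
#' Because (Y, Z) given R is normal with common covariance across the two R
#' groups, the induced observation model is exactly logistic-linear in
#' (Y, Z); the coefficients follow from the equal-covariance normal
#' discriminant.
#'
#' @param config An [generator_config()].
#' @return Named vector (intercept, Y, Z).
#' @export
true_alpha <- function(config) {
  g1 <- yz_given_r(config, 1); g0 <- yz_given_r(config, 0)
  s_inv_d <- solve(g1$cov, g1$mean - g0$mean)
  intercept <- log(config$p_r / (1 - config$p_r)) -
    0.5 * sum((g1$mean + g0$mean) * s_inv_d)
  stats::setNames(c(intercept, s_inv_d), c("1", "Y", "Z"))
}

#' True optimal augmentation implied by the generator
#'
#' The exact `phi_opt(Y, Z, beta) = -E[d(X,Z) eps(beta) | Y, Z, R = 1]`
#' under the generator's joint-normal law, assembled from the closed-form
#' conditional moments `E(X | Y, Z, R = 1)` and `E(X^2 | Y, Z, R = 1)`
#' (conditional-normal formulas), for the linear mean model with
#' homoscedastic index.
#'
#' @param config An [generator_config()].
#' @return An `acc_phi` usable with [fit_acc()] on any dataset with one X
#'   and one Z column.
#' @export
true_phi_opt <- function(config) {
  cf <- config
  b <- cf$beta_true[2:3]
  g1 <- yz_given_r(cf, 1)
  sb <- drop(cf$sigma_xz %*% b)
  cx <- c(sb[1], cf$sigma_xz[1, 2])     # Cov(X, (Y, Z)) given R = 1
  s_inv_cx <- solve(g1$cov, cx)
  v_cond <- cf$sigma_xz[1, 1] - sum(cx * s_inv_cx)
  mx <- cf$mu1[1]
  new_phi("true_opt", function(data, beta) {
    dev <- cbind(data$y - g1$mean[1], drop(data$z) - g1$mean[2])
    m1 <- mx + drop(dev %*% s_inv_cx)
    m2 <- m1^2 + v_cond
    phi_from_moments(m1, m2, data$y, data$z, beta)
  }, meta = list(v_cond = v_cond), affine = TRUE)
}

#' Run a Monte-Carlo simulation study
#'
#' Generates `reps` datasets from the configuration (independent child
#' seeds spawned from the master seed), fits the requested estimators on
#' each, and aggregates bias, empirical SD and 95% confidence-interval
#' coverage per estimator and coefficient. A failed replication for an
#' estimator is counted and skipped, never fatal.
#'
#' Available estimators: `"CCA"`, `"MI"` (M = 10 proper imputations),
#' `"IPW"`, `"ACC-TRUE"` (true optimal augmentation), `"ACC-WM1"` /
#' `"ACC2-WM1"` (correct working-model basis 1, Y, Z; m = 10 draws),
#' `"ACC-WM2"` / `"ACC2-WM2"` (mis-specified basis 1, Y^2, Z^2),
#' `"ACC-NP"` (kernel augmentation frozen at the complete-case estimate),
#' `"ACC-NP2"` (kernel conditional-moment augmentation). Kernel bandwidths
#' follow [default_bandwidths()].
#'
#' @param config An [generator_config()].
#' @param reps Number of replications.
#' @param estimators Character vector of estimator labels (default: all).
#' @param seed Master seed.
#' @return A tibble of class `acc_study` with columns `estimator`, `term`,
#'   `mean`, `sd`, `coverage` (percent), `reps_used`, `failures`; the
#'   per-replication estimates are kept in `attr(, "estimates")` and the
#'   configuration in `attr(, "config")`.
#' @export
run_study <- function(config, reps = 1000L,
                      estimators = study_estimators(), seed = 1L) {
  stopifnot(reps >= 1)
  estimators <- match.arg(estimators, study_estimators(),
                          several.ok = TRUE)
  seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L, 4L * reps), reps, 4L)
  })
  truth <- config$beta_true
  terms <- c("(Intercept)", "X", "Z")
  model <- mean_model("linear", p = 1, q = 1)
  phi_true <- if ("ACC-TRUE" %in% estimators) true_phi_opt(config)
  rows <- vector("list", reps)
  failures <- stats::setNames(integer(length(estimators)), estimators)
  for (i in seq_len(reps)) {
    data <- generate_dataset(config, seeds[i, 1])
    mfit <- tryCatch(
      fit_missingness(data, missingness_design(c("1", "Y", "Z"))),
      error = function(e) NULL)
    cca <- tryCatch(fit_cca(model, data), error = function(e) NULL)
    wm_phi <- function(basis, sd_col) {
      wm <- fit_working_model(data, basis)
      phi_working_model(model, wm, m = 10L, seed = seeds[i, sd_col])
    }
    kspec <- NULL
    get_kspec <- function() {
      if (is.null(kspec)) kspec <<- default_bandwidths(data)
      kspec
    }
    one <- function(label) {
      if (is.null(cca) || (label != "CCA" && label != "MI" && is.null(mfit))) {
        stop("prerequisite fit failed")
      }
      switch(label,
        "CCA" = cca,
        "MI" = fit_mi(model, data, basis = c("1", "Y", "Z"), M = 10L,
                      seed = seeds[i, 4]),
        "IPW" = fit_ipw(model, data, mfit),
        "ACC-TRUE" = fit_acc(model, data, mfit, phi_true, label),
        "ACC-WM1" = fit_acc(model, data, mfit,
                            wm_phi(c("1", "Y", "Z"), 2), label),
        "ACC2-WM1" = fit_acc2(model, data, mfit,
                              wm_phi(c("1", "Y", "Z"), 2), label),
        "ACC-WM2" = fit_acc(model, data, mfit,
                            wm_phi(c("1", "Y^2", "Z^2"), 3), label),
        "ACC2-WM2" = fit_acc2(model, data, mfit,
                              wm_phi(c("1", "Y^2", "Z^2"), 3), label),
        "ACC-NP" = fit_acc(model, data, mfit,
                           phi_kernel_direct(model, data,
                                             unname(cca$beta_hat),
                                             get_kspec()), label),
        "ACC-NP2" = fit_acc(model, data, mfit,
                            phi_kernel_moments(model, data, get_kspec()),
                            label)
      )
    }
    res_i <- lapply(estimators, function(lab) {
      fit <- tryCatch(one(lab), error = function(e) NULL)
      if (is.null(fit)) {
        failures[lab] <<- failures[lab] + 1L
        return(NULL)
      }
      tibble::tibble(
        rep = i, estimator = lab, term = terms,
        estimate = unname(fit$beta_hat), se = unname(fit$se),
        covered = truth >= fit$ci_low & truth <= fit$ci_high
      )
    })
    rows[[i]] <- dplyr::bind_rows(res_i)
  }
  est <- dplyr::bind_rows(rows)
  fail_tbl <- tibble::tibble(estimator = names(failures),
                             failures = unname(failures))
  out <- est |>
    dplyr::group_by(.data$estimator, .data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      sd = stats::sd(.data$estimate),
      coverage = 100 * mean(.data$covered),
      reps_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(fail_tbl, by = "estimator") |>
    dplyr::mutate(
      estimator = factor(.data$estimator, levels = estimators),
      term = factor(.data$term, levels = terms)
    ) |>
    dplyr::arrange(.data$estimator, .data$term) |>
    dplyr::mutate(estimator = as.character(.data$estimator),
                  term = as.character(.data$term))
  attr(out, "estimates") <- est
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "reps") <- reps
  class(out) <- c("acc_study", class(out))
  out
}

#' @rdname run_study
#' @export
study_estimators <- function() {
  c("CCA", "MI", "IPW", "ACC-TRUE", "ACC-WM1", "ACC2-WM1",
    "ACC-WM2", "ACC2-WM2", "ACC-NP", "ACC-NP2")
}

#' Plot a simulation study summary
#'
#' Point-range plot of the mean estimate with +/- one empirical SD per
#' estimator, faceted by coefficient, with the true value as a reference
#' line.
#'
#' @param object An `acc_study` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.acc_study <- function(object, ...) {
  truth <- tibble::tibble(
    term = c("(Intercept)", "X", "Z"),
    truth = attr(object, "config")$beta_true
  )
  df <- dplyr::left_join(tibble::as_tibble(object), truth, by = "term")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimator, y = .data$mean)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean estimate ± empirical SD")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
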