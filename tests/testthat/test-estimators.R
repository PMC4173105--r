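test_that("CCA equals closed-form least squares and ignores incomplete rows", {
  set.seed(2)
  df <- data.frame(Y = rnorm(40), X = rnorm(40), Z = rnorm(40))
  d <- acc_data(df, "Y", "X", "Z")
  m <- mean_model("linear", p = 1, q = 1)
  fit <- fit_cca(m, d)
  xm <- cbind(1, df$X, df$Z)
  beta_ne <- drop(solve(crossprod(xm), crossprod(xm, df$Y)))
  expect_equal(unname(fit$beta_hat), beta_ne, tolerance = 1e-10)

  df2 <- rbind(df, data.frame(Y = 99, X = NA, Z = -3))
  fit2 <- fit_cca(m, acc_data(df2, "Y", "X", "Z"))
  expect_equal(unname(fit2$beta_hat), beta_ne, tolerance = 1e-10)
  expect_lte(fit$diagnostics$ee_norm, 1e-8)
})

test_that("phi-tilde projection removes the score span and nothing else", {
  cfg <- generator_config(n = 60)
  d <- generate_dataset(cfg, 31)
  mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
  h <- mf$design_rows
  # phi inside the score span projects to zero
  expect_lt(max(abs(project_phi_tilde(h, mf))), 1e-10)
  # phi weighted-orthogonal to the span is untouched
  w <- score_weights(mf)
  phi <- matrix(rnorm(60 * 3), 60, 3)
  phi_orth <- phi - h %*% solve(crossprod(h, w * h), crossprod(w * h, phi))
  expect_equal(project_phi_tilde(phi_orth, mf), phi_orth, tolerance = 1e-9)
  # after projection, weighted orthogonality holds by construction
  pt <- project_phi_tilde(phi, mf)
  expect_lt(max(abs(crossprod(w * h, pt))), 1e-8)
})

test_that("phi-tilde projection matches hand arithmetic on two subjects", {
  # intercept-only design: h = (1, 1); w_i = pi_i (1 - pi_i)
  mfit <- structure(list(
    pi_hat = c(0.5, 0.9),
    design_rows = matrix(1, 2, 1)
  ), class = "acc_miss_fit")
  phi <- matrix(c(2, -1), 2, 1)
  w <- c(0.25, 0.09)
  b <- sum(w * phi) / sum(w)
  expect_equal(project_phi_tilde(phi, mfit), phi - b, ignore_attr = TRUE)
})

test_that("ACC with the zero augmentation reproduces CCA exactly", {
  cfg <- generator_config(n = 150)
  d <- generate_dataset(cfg, 7)
  m <- mean_model("linear", p = 1, q = 1)
  mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
  cca <- fit_cca(m, d)
  acc <- fit_acc(m, d, mf, phi_zero(3))
  expect_equal(unname(acc$beta_hat), unname(cca$beta_hat), tolerance = 1e-10)
  expect_equal(acc$vcov, cca$vcov, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("influence contributions average to zero at the solution", {
  cfg <- generator_config(n = 400)
  d <- generate_dataset(cfg, 19)
  m <- mean_model("linear", p = 1, q = 1)
  mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
  wm <- fit_working_model(d, c("1", "Y", "Z"))
  phi <- phi_working_model(m, wm, m = 10, seed = 5)
  fits <- list(
    fit_cca(m, d),
    fit_acc(m, d, mf, phi),
    fit_acc2(m, d, mf, phi),
    fit_ipw(m, d, mf)
  )
  for (f in fits) {
    expect_lt(max(abs(colMeans(f$influence))), 1e-6, label = f$label)
    expect_equal(f$vcov, t(f$vcov), tolerance = 1e-10)
    expect_equal(unname(f$se), unname(sqrt(diag(f$vcov))))
    expect_equal(unname(f$ci_low),
                 unname(f$beta_hat - 1.959964 * f$se))
  }
})

test_that("ACC2 never reports more variance than CCA and handles degeneracy", {
  m <- mean_model("linear", p = 1, q = 1)
  for (seed in c(3, 14, 27)) {
    cfg <- generator_config(n = 250)
    d <- generate_dataset(cfg, seed)
    mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
    cca <- fit_cca(m, d)
    # a deliberately poor augmentation: mis-specified quadratic working model
    wm <- fit_working_model(d, c("1", "Y^2", "Z^2"))
    phi <- phi_working_model(m, wm, m = 10, seed = seed)
    a2 <- fit_acc2(m, d, mf, phi)
    expect_true(all(diag(a2$vcov) <= diag(cca$vcov) + 1e-12))
  }
  cfg <- generator_config(n = 200)
  d <- generate_dataset(cfg, 40)
  mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
  cca <- fit_cca(m, d)
  expect_warning(a0 <- fit_acc2(m, d, mf, phi_zero(3)), "degenerate")
  expect_equal(unname(a0$beta_hat), unname(cca$beta_hat), tolerance = 1e-12)
})

test_that("an augmentation uncorrelated with the CC term leaves ACC2 near CCA", {
  cfg <- generator_config(n = 4000)
  d <- generate_dataset(cfg, 77)
  m <- mean_model("linear", p = 1, q = 1)
  mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
  noise_phi <- local({
    set.seed(123)
    v <- matrix(rnorm(4000 * 3), 4000, 3)
    structure(list(label = "noise", affine = TRUE,
                   eval = function(data, beta) v, meta = list()),
              class = "acc_phi")
  })
  cca <- fit_cca(m, d)
  a2 <- fit_acc2(m, d, mf, noise_phi)
  gamma <- a2$diagnostics$gamma
  expect_lt(max(abs(gamma)), 0.2)
  expect_lt(max(abs(a2$beta_hat - cca$beta_hat)), 0.05)
})

test_that("IPW with constant weights equals CCA; stacked sandwich is sane", {
  cfg <- generator_config(n = 200)
  d <- generate_dataset(cfg, 9)
  m <- mean_model("linear", p = 1, q = 1)
  mf0 <- fit_missingness(d, missingness_design("1"))
  cca <- fit_cca(m, d)
  ipw <- fit_ipw(m, d, mf0)
  expect_equal(unname(ipw$beta_hat), unname(cca$beta_hat), tolerance = 1e-8)
  expect_true(all(diag(ipw$vcov) > 0))
})

test_that("proper imputation is Bayesian-correct in distribution", {
  d <- acc_data(
    data.frame(Y = c(0.1, 1.3, 2.2, 2.8, 4.1, 5.2, 1.7, 3.3),
               X = c(0.3, 1.1, NA, 2.6, NA, 5.0, 1.5, 3.1)),
    "Y", "X")
  # unchanged when nothing is missing
  d_full <- acc_data(data.frame(Y = 1:5 + 0.0, X = c(1, 3, 2, 5, 4)), "Y", "X")
  expect_identical(impute_proper(d_full, c("1", "Y")), d_full)
  # posterior-predictive mean at a missing row equals the OLS fitted value
  cc <- which(d$r == 1)
  ols <- coef(lm(d$x[cc, 1] ~ d$y[cc]))
  fitted_mis <- ols[1] + ols[2] * d$y[d$r == 0]
  set.seed(6)
  draws <- replicate(4000, impute_proper(d, c("1", "Y"))$x[d$r == 0, 1])
  mc_se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - fitted_mis) < 3 * mc_se))
  # degenerate (exactly collinear) data is refused
  d_exact <- acc_data(data.frame(Y = c(0, 1, 2, 3, 4, 5),
                                 X = c(0, 2, 4, 6, 8, NA)), "Y", "X")
  expect_error(impute_proper(d_exact, c("1", "Y")), "degenerate")
})

test_that("Rubin pooling follows the hand formula and collapses without missingness", {
  p <- pool_rubin(matrix(c(0, 2)), list(matrix(1), matrix(1)))
  expect_equal(drop(p$beta), 1)
  expect_equal(drop(p$between), 2)
  expect_equal(drop(p$vcov), 4)      # 1 + 1.5 * 2

  set.seed(3)
  df <- data.frame(Y = rnorm(30), X = rnorm(30), Z = rnorm(30))
  d <- acc_data(df, "Y", "X", "Z")
  m <- mean_model("linear", p = 1, q = 1)
  mi <- fit_mi(m, d, M = 3, seed = 10)
  full <- fit_full_data(m, d)
  expect_equal(unname(mi$beta_hat), unname(full$beta_hat), tolerance = 1e-10)
  expect_equal(max(abs(mi$diagnostics$between)), 0)
})

test_that("root-based estimators match a brute-force oracle on six subjects", {
  d <- hand_data()
  m <- mean_model("linear", p = 1, q = 1)
  mf <- fit_missingness(d, missingness_design(c("1", "Y")))
  cca <- fit_cca(m, d)
  expect_equal(unname(cca$beta_hat), oracle_root(function(b) oracle_ee_cca(d, b)),
               tolerance = 1e-6)

  phi <- phi_kernel_moments(m, d, structure(list(h = c(1, 1)),
                                            class = "acc_kernel_spec"))
  acc <- fit_acc(m, d, mf, phi)
  phi_fun <- function(i, beta) {
    m1 <- phi$meta$m1[i]; m2 <- phi$meta$m2[i]
    y <- d$y[i]; z <- d$z[i, 1]
    c(-(y - beta[1] - beta[2] * m1 - beta[3] * z),
      -(m1 * (y - beta[1] - beta[3] * z) - beta[2] * m2),
      -z * (y - beta[1] - beta[2] * m1 - beta[3] * z))
  }
  expect_equal(
    unname(acc$beta_hat),
    oracle_root(function(b) oracle_ee_acc(d, b, mf$pi_hat, phi_fun)),
    tolerance = 1e-6)

  ipw <- fit_ipw(m, d, mf)
  ee_ipw <- function(b) {
    out <- numeric(3)
    for (i in seq_len(d$n)) {
      if (d$r[i] == 1) {
        di <- c(1, d$x[i, ], d$z[i, ])
        out <- out + di * (d$y[i] - sum(di * b)) / mf$pi_hat[i]
      }
    }
    out
  }
  expect_equal(unname(ipw$beta_hat), oracle_root(ee_ipw), tolerance = 1e-6)
})

test_that("the Newton path agrees with the direct affine solve", {
  cfg <- generator_config(n = 200)
  d <- generate_dataset(cfg, 55)
  m <- mean_model("linear", p = 1, q = 1)
  mf <- fit_missingness(d, missingness_design(c("1", "Y", "Z")))
  phi <- true_phi_opt(cfg)
  direct <- fit_acc(m, d, mf, phi)
  # same evaluator, declared non-affine: forces the Newton path
  phi_newton <- structure(list(label = "true_opt", eval = phi$eval,
                               meta = phi$meta, affine = FALSE),
                          class = "acc_phi")
  newton <- fit_acc(m, d, mf, phi_newton)
  expect_equal(unname(direct$beta_hat), unname(newton$beta_hat),
               tolerance = 1e-8)
  expect_equal(direct$diagnostics$method, "direct")
  expect_equal(newton$diagnostics$method, "newton")
})

test_that("all estimators recover the truth when missingness depends on Z only", {
  reps <- 150
  st <- run_study(mar_z_config(n = 1000), reps = reps, seed = 104)
  tab <- as.data.frame(st)
  truth <- c("(Intercept)" = 0, X = 0.2, Z = 0.2)
  for (k in seq_len(nrow(tab))) {
    mc_se <- tab$sd[k] / sqrt(tab$reps_used[k])
    expect_lt(abs(tab$mean[k] - truth[[tab$term[k]]]), 3 * mc_se,
              label = paste(tab$estimator[k], tab$term[k]))
  }
})
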