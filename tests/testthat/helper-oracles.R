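# Test-side oracles, written independently of the package internals.

# a fixed 6-row dataset with one covariate observed for 4 subjects
hand_data <- function() {
  acc_data(
    data.frame(
      Y = c(1.2, -0.4, 0.3, 2.1, -1.0, 0.6),
      X = c(0.5, -1.1, 0.9, NA, NA, 0.2),
      Z = c(0.3, -0.2, 1.1, 0.4, -0.8, 0.0)
    ),
    outcome = "Y", x_cols = "X", z_cols = "Z"
  )
}

# plain-loop estimating functions (independent of the package's vectorised
# implementations); linear mean with homoscedastic index d = (1, x, z)
oracle_ee_cca <- function(data, beta) {
  out <- numeric(length(beta))
  for (i in seq_len(data$n)) {
    if (data$r[i] == 1) {
      d_i <- c(1, data$x[i, ], data$z[i, ])
      eps <- data$y[i] - sum(d_i * beta)
      out <- out + d_i * eps
    }
  }
  out
}

oracle_ee_acc <- function(data, beta, pi_hat, phi_fun) {
  out <- oracle_ee_cca(data, beta)
  for (i in seq_len(data$n)) {
    out <- out + (data$r[i] - pi_hat[i]) * phi_fun(i, beta)
  }
  out
}

# brute-force root: minimise the squared estimating-function norm from
# several starting points with derivative-free and gradient methods
oracle_root <- function(ee, d = 3) {
  obj <- function(b) sum(ee(b)^2)
  starts <- rbind(rep(0, d), rep(0.5, d), c(1, -1, 1)[seq_len(d)])
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o1 <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-16))
    if (is.null(best) || o2$value < best$value) best <- o2
  }
  best$par
}

# mean and covariance of (X, Y, Z) given R = 1 implied by a generator
# configuration, assembled by direct moment algebra
oracle_joint_r1 <- function(cfg) {
  b0 <- cfg$beta_true[1]; bx <- cfg$beta_true[2]; bz <- cfg$beta_true[3]
  s <- cfg$sigma_xz
  mx <- cfg$mu1[1]; mz <- cfg$mu1[2]
  my <- b0 + bx * mx + bz * mz
  vxx <- s[1, 1]; vxz <- s[1, 2]; vzz <- s[2, 2]
  vxy <- bx * vxx + bz * vxz
  vzy <- bx * vxz + bz * vzz
  vyy <- bx^2 * vxx + 2 * bx * bz * vxz + bz^2 * vzz + cfg$sigma_eps2
  list(
    mean = c(X = mx, Y = my, Z = mz),
    cov = matrix(c(vxx, vxy, vxz,
                   vxy, vyy, vzy,
                   vxz, vzy, vzz), 3, 3, byrow = TRUE,
                 dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  )
}

# conditional mean/variance of X given (Y, Z) = (y, z), R = 1
oracle_x_given_yz <- function(cfg, y, z) {
  j <- oracle_joint_r1(cfg)
  s_yz <- j$cov[c("Y", "Z"), c("Y", "Z")]
  c_x <- j$cov["X", c("Y", "Z")]
  w <- solve(s_yz, c_x)
  m1 <- j$mean["X"] + cbind(y - j$mean["Y"], z - j$mean["Z"]) %*% w
  v <- j$cov["X", "X"] - sum(c_x * w)
  list(m1 = drop(m1), v = v)
}

# quadrature evaluation of -E[d(X,Z) eps(beta) | y, z, R=1], linear mean
oracle_phi_quadrature <- function(cfg, y, z, beta) {
  cond <- oracle_x_given_yz(cfg, y, z)
  sdv <- sqrt(cond$v)
  comp <- function(dfun) {
    -stats::integrate(function(x) {
      eps <- y - beta[1] - beta[2] * x - beta[3] * z
      dfun(x) * eps * stats::dnorm(x, cond$m1, sdv)
    }, cond$m1 - 10 * sdv, cond$m1 + 10 * sdv,
    rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  c(comp(function(x) 1), comp(function(x) x), comp(function(x) z))
}

# a generator configuration whose missingness depends on Z only (MAR via Z):
# no X mean shift between the R groups
mar_z_config <- function(n = 1000) {
  generator_config(n = n, mu0 = c(0, -0.25), mu1 = c(0, 0.25))
}
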