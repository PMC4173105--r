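#' Design for the observation-probability model P(R = 1 | Y, Z)
#'
#' The probability that the X block is observed is modelled as
#' `expit(h(Y, Z; alpha))` with `h` linear in `alpha`, so the design is a
#' basis over the fully observed variables. Terms are given as strings:
#' `"1"` (intercept), `"Y"`, `"Y^2"`, a Z column name, or a Z column name
#' followed by `"^2"` (e.g. `"age^2"`). Because `h` is linear in `alpha`,
#' the gradient `h_alpha(Y, Z)` equals the design row itself.
#'
#' @param terms Character vector of term names.
#' @return An object of class `acc_miss_design`: a list with `terms` and a
#'   function `build(data)` returning the n x k design matrix.
#' @examples
#' missingness_design(c("1", "Y", "Z"))
#' @export
missingness_design <- function(terms = c("1", "Y")) {
  stopifnot(is.character(terms), length(terms) >= 1)
  build <- function(data) {
    col_of <- function(term) {
      sq <- grepl("\\^2$", term)
      base <- sub("\\^2$", "", term)
      v <- if (base == "1") {
        rep(1, data$n)
      } else if (base == "Y") {
        data$y
      } else if (base %in% colnames(data$z)) {
        data$z[, base]
      } else {
        stop("unknown missingness design term '", term,
             "': use \"1\", \"Y\", a Z column name, or any of these with ^2")
      }
      if (sq) v^2 else v
    }
    h <- vapply(terms, col_of, numeric(data$n))
    dim(h) <- c(data$n, length(terms))
    colnames(h) <- terms
    h
  }
  structure(list(terms = terms, build = build), class = "acc_miss_design")
}

#' Fit the logistic observation model P(R = 1 | Y, Z; alpha) by ML
#'
#' Maximises the Bernoulli likelihood of the observation indicator given the
#' design by Newton-Raphson on the score
#' `sum_i (r_i - pi_i) h_alpha(y_i, z_i)`, with step-halving; convergence is
#' declared when the max-abs score is at most `tol`. The score equations are
#' the exact estimating functions reused by [project_phi_tilde()], which is
#' why the fit exposes the design rows and fitted probabilities.
#'
#' @param data An [acc_data()] object with both complete and incomplete cases.
#' @param design An [missingness_design()]; default intercept + Y + all Z.
#' @param tol Convergence tolerance on the max-abs score.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `acc_miss_fit` with `alpha_hat`, `pi_hat`,
#'   `design_rows`, `terms`, `converged`, `score_norm`, `iterations`.
#' @examples
#' d <- acc_data(data.frame(Y = 1:4, X = c(1, 2, NA, NA)), "Y", "X")
#' f <- fit_missingness(d, missingness_design("1"))
#' f$alpha_hat # logit of mean(R) = 0
#' @export
fit_missingness <- function(data, design = NULL, tol = 1e-8, max_iter = 100L) {
  if (is.null(design)) {
    design <- missingness_design(c("1", "Y", colnames(data$z)))
  }
  r <- data$r
  if (all(r == 1L)) stop("no incomplete cases: all subjects have X observed")
  if (all(r == 0L)) stop("no complete cases: all subjects have X missing")
  h <- design$build(data)
  k <- ncol(h)
  if (k > data$n) stop("more design terms than subjects")
  if (qr(h)$rank < k) stop("singular missingness design")

  alpha <- numeric(k)
  score <- function(a) {
    pi <- expit(drop(h %*% a))
    drop(crossprod(h, r - pi))
  }
  s <- score(alpha)
  iter <- 0L
  repeat {
    if (max(abs(s)) <= tol || iter >= max_iter) break
    iter <- iter + 1L
    pi <- expit(drop(h %*% alpha))
    w <- pi * (1 - pi)
    info <- crossprod(h, w * h)
    step <- tryCatch(solve(info, s), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix in the observation-model fit; ",
           "try a simpler missingness design")
    }
    # step-halving on the score norm
    f0 <- sum(s^2)
    lam <- 1
    repeat {
      cand <- alpha + lam * step
      s_cand <- score(cand)
      if (sum(s_cand^2) < f0 || lam < 1e-8) break
      lam <- lam / 2
    }
    alpha <- cand
    s <- s_cand
  }
  converged <- max(abs(s)) <= tol
  if (!converged || max(abs(alpha)) > 30) {
    stop("observation-model ML did not converge (max-abs score ",
         format(max(abs(s)), digits = 3), " after ", iter, " iterations); ",
         "this can indicate perfect separation - try a simpler missingness design")
  }
  pi_hat <- expit(drop(h %*% alpha))
  structure(
    list(alpha_hat = stats::setNames(alpha, colnames(h)), pi_hat = pi_hat,
         design_rows = h, terms = design$terms, converged = converged,
         score_norm = max(abs(s)), iterations = iter),
    class = "acc_miss_fit"
  )
}

#' @export
print.acc_miss_fit <- function(x, ...) {
  cat("<acc_miss_fit> logistic P(R=1|Y,Z), terms:",
      paste(x$terms, collapse = ", "), "\n")
  print(round(x$alpha_hat, 4))
  cat("max-abs score:", format(x$score_norm, digits = 3),
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Score weights pi(1 - pi) of the fitted observation model
#'
#' The weights appearing in the projection of the augmentation function on
#' the alpha-score space; each lies in (0, 0.25].
#'
#' @param fit An `acc_miss_fit`.
#' @return Numeric vector of length n.
#' @export
score_weights <- function(fit) {
  fit$pi_hat * (1 - fit$pi_hat)
}
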