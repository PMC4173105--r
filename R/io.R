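#' Serialize fitted estimators to JSON
#'
#' Writes a JSON document keyed by estimator label, each entry holding the
#' coefficient vector, standard errors, 95% confidence limits, the
#' covariance matrix (row-major) and scalar diagnostics. Numbers are
#' written at 17 significant digits so a write/read round trip is lossless.
#'
#' @param results A list of `acc_fit` objects (possibly empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_acc_results <- function(results, path) {
  stopifnot(is.list(results))
  ser <- list()
  for (f in results) {
    stopifnot(inherits(f, "acc_fit"))
    dg <- f$diagnostics
    ser[[f$label]] <- list(
      beta = as.list(f$beta_hat),
      se = as.list(stats::setNames(f$se, names(f$beta_hat))),
      ci_low = as.list(stats::setNames(f$ci_low, names(f$beta_hat))),
      ci_high = as.list(stats::setNames(f$ci_high, names(f$beta_hat))),
      vcov = as.vector(t(f$vcov)),
      coef_names = names(f$beta_hat),
      diagnostics = list(
        iterations = dg$iterations %||% NA_integer_,
        ee_norm = dg$ee_norm %||% NA_real_,
        converged = isTRUE(dg$converged),
        n = f$n
      )
    )
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read back serialized estimator results
#'
#' @param path JSON file written by [write_acc_results()].
#' @return A named list; each element has `beta`, `se`, `ci_low`,
#'   `ci_high` (named vectors) and `vcov` (matrix).
#' @export
read_acc_results <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(e) {
    d <- length(e$coef_names)
    list(
      beta = unlist(e$beta), se = unlist(e$se),
      ci_low = unlist(e$ci_low), ci_high = unlist(e$ci_high),
      vcov = matrix(e$vcov, d, d, byrow = TRUE,
                    dimnames = list(e$coef_names, e$coef_names)),
      diagnostics = e$diagnostics
    )
  })
}

#' Fit one or more estimators on a dataset, by label
#'
#' Thin dispatcher used by the command-line front end: fits the observation
#' model once and each requested estimator on top of it. Methods follow
#' [run_study()] labelling with the working-model/kernel choices exposed as
#' arguments instead of fixed rosters.
#'
#' @param data An [acc_data()].
#' @param methods Character vector among `"cca"`, `"acc-wm"`, `"acc2-wm"`,
#'   `"acc-np"`, `"acc-np2"`, `"ipw"`, `"mi"`, `"full"`.
#' @param kind Mean-model kind (`"linear"` or `"logistic"`).
#' @param missingness Terms of the observation-model design (default
#'   intercept + Y + all Z columns); [missingness_design()] syntax, which
#'   admits quadratic terms such as `"Y^2"` and transformed Z columns.
#' @param wm_basis Working-model / imputation basis over (Y, Z).
#' @param m Monte-Carlo draws for the working-model augmentation.
#' @param M Number of proper imputations for MI.
#' @param seed Seed for Monte-Carlo draws and imputations.
#' @return Named list of `acc_fit` objects.
#' @export
acc_analysis <- function(data,
                         methods = "cca",
                         kind = "linear",
                         missingness = NULL,
                         wm_basis = NULL,
                         m = 10L, M = 10L, seed = 1L) {
  known <- c("cca", "acc-wm", "acc2-wm", "acc-np", "acc-np2", "ipw", "mi",
             "full")
  bad <- setdiff(methods, known)
  if (length(bad) > 0) {
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "))
  }
  model <- mean_model(kind, p = data$p, q = data$q)
  needs_miss <- any(methods %in% c("acc-wm", "acc2-wm", "acc-np", "acc-np2",
                                   "ipw"))
  mfit <- if (needs_miss) {
    fit_missingness(data, if (is.null(missingness)) NULL else
      missingness_design(missingness))
  }
  cca <- fit_cca(model, data)
  wm_phi <- function() {
    phi_working_model(model, fit_working_model(data, wm_basis),
                      m = m, seed = seed)
  }
  out <- lapply(methods, function(meth) {
    switch(meth,
      "cca" = cca,
      "full" = fit_full_data(model, data),
      "ipw" = fit_ipw(model, data, mfit),
      "mi" = fit_mi(model, data, basis = wm_basis, M = M, seed = seed),
      "acc-wm" = fit_acc(model, data, mfit, wm_phi(), "ACC-WM"),
      "acc2-wm" = fit_acc2(model, data, mfit, wm_phi(), "ACC2-WM"),
      "acc-np" = fit_acc(model, data, mfit,
                         phi_kernel_direct(model, data, unname(cca$beta_hat),
                                           default_bandwidths(data)),
                         "ACC-NP"),
      "acc-np2" = fit_acc(model, data, mfit,
                          phi_kernel_moments(model, data,
                                             default_bandwidths(data)),
                          "ACC-NP2")
    )
  })
  stats::setNames(out, vapply(out, function(f) f$label, character(1)))
}

#' Write a study summary as CSV
#'
#' @param study An `acc_study` from [run_study()].
#' @param path Output CSV path (rows = estimator x coefficient).
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  utils::write.csv(as.data.frame(study), path, row.names = FALSE)
  invisible(path)
}
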