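#' Convert polarization to anisotropy
#'
#' `A = 2P / (3 - P)` with polarization `P` in fraction units (divide mP
#' readings by 1000 first, or use `mP = TRUE`).
#'
#' @param P polarization, fraction units in (-1, 1) unless `mP = TRUE`.
#' @param mP if TRUE, `P` is in milli-polarization units and divided by 1000.
#' @return Anisotropy, same length as `P`.
#' @examples
#' polarization_to_anisotropy(0.5)        # 0.4
#' polarization_to_anisotropy(20, mP = TRUE)
#' @export
polarization_to_anisotropy <- function(P, mP = FALSE) {
  if (mP) P <- P / 1000
  if (any(!is.finite(P)) || any(P <= -1) || any(P >= 1)) {
    stop("polarization must lie in (-1, 1) fraction units")
  }
  2 * P / (3 - P)
}

#' Convert anisotropy back to polarization
#'
#' Algebraic inverse of [polarization_to_anisotropy()]: `P = 3A / (2 + A)`.
#'
#' @param A anisotropy.
#' @param mP if TRUE, return milli-polarization units.
#' @return Polarization.
#' @export
anisotropy_to_polarization <- function(A, mP = FALSE) {
  P <- 3 * A / (2 + A)
  if (mP) P * 1000 else P
}

#' Scale a titration series to a requested baseline polarization
#'
#' Plate readers request a gain such that a reference well reads a chosen
#' polarization. Measurements are rescaled proportionally so that the lowest
#' protein concentration (the last point of a serial dilution) reads exactly
#' `requested_mP` (default 20 mP).
#'
#' @param series data.frame with columns `concentration_uM` and `mP`.
#' @param requested_mP target polarization for the lowest-concentration
#'   point, milli-polarization units.
#' @return The series with `mP` rescaled.
#' @export
scale_series <- function(series, requested_mP = 20) {
  stopifnot(nrow(series) > 0,
            all(c("concentration_uM", "mP") %in% names(series)))
  anchor <- series$mP[which.min(series$concentration_uM)][1]
  if (!is.finite(anchor) || anchor <= 0) {
    stop("scaling refused: polarization at the lowest concentration is <= 0")
  }
  series$mP <- series$mP * (requested_mP / anchor)
  series
}

# specific binding with Hill slope on anisotropy
hill_model <- function(x, kd, hill, amax, baseline) {
  baseline + (amax - baseline) * x^hill / (kd^hill + x^hill)
}

#' Fit the specific-binding-with-Hill-slope model to an FP titration
#'
#' Converts polarization (mP) to anisotropy and fits
#' `A(x) = baseline + (amax - baseline) * x^h / (Kd^h + x^h)`
#' by bounded Levenberg-Marquardt least squares. Initial values: Kd at the
#' geometric mid-concentration, Hill slope 1, amax at the maximum observed
#' anisotropy, baseline at the minimum; three seeded random restarts are
#' attempted on non-convergence. A fitted baseline absorbs the instrument
#' offset at zero binding; set `constrain_baseline = TRUE` to fix it at 0.
#'
#' The fit is flagged unreliable when the estimated Kd falls outside the
#' measured concentration range extended by a factor of 100 on either side
#' (a Kd too weak — or too tight — to be determined from the design). Ligand
#' depletion is ignored; a warning fires when the estimated Kd is within
#' 10x the ligand concentration, where free and total protein diverge.
#'
#' @param series data.frame with columns `concentration_uM` (protein, > 0)
#'   and either `mP` (milli-polarization) or `anisotropy`. At least 6 points.
#' @param ligand_nM fixed fluorescent ligand concentration (nM, default 10).
#' @param constrain_baseline fix the baseline at 0 instead of fitting it.
#' @param scale_to_mP if non-NULL, apply [scale_series()] with this request
#'   before converting.
#' @param seed integer seed for the restart jitter.
#' @return Object of class `fp_fit`: estimates `kd` (uM), `hill`, `amax`,
#'   `baseline`, their standard errors, `converged`, `reliable`, residual
#'   summary and the fitted data.
#' @export
fit_fp_binding <- function(series, ligand_nM = 10, constrain_baseline = FALSE,
                           scale_to_mP = NULL, seed = 1L) {
  stopifnot(is.data.frame(series), "concentration_uM" %in% names(series))
  if (!is.null(scale_to_mP)) series <- scale_series(series, scale_to_mP)
  x <- series$concentration_uM
  if (any(x <= 0)) stop("protein concentrations must be positive")
  A <- if ("anisotropy" %in% names(series)) series$anisotropy
       else polarization_to_anisotropy(series$mP, mP = TRUE)
  if (length(unique(x)) < 6) stop("need at least 6 titration points to fit")

  dat <- data.frame(x = x, A = A)
  start0 <- list(kd = exp(mean(log(range(x)))), hill = 1,
                 amax = max(A), baseline = min(A))
  lower <- c(kd = 1e-6, hill = 0.1, amax = -Inf, baseline = -Inf)
  upper <- c(kd = 1e6, hill = 10, amax = Inf, baseline = Inf)
  form <- A ~ baseline + (amax - baseline) * x^hill / (kd^hill + x^hill)
  if (constrain_baseline) {
    form <- A ~ (amax) * x^hill / (kd^hill + x^hill)
    start0$baseline <- NULL
    lower <- lower[names(lower) != "baseline"]
    upper <- upper[names(upper) != "baseline"]
  }

  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- try_fit(start0)
  if (is.null(fit)) {
    rng <- with_seed(seed,
      lapply(1:3, function(i)
        lapply(start0, function(v) v * exp(stats::runif(1, -1, 1)))))
    for (start in rng) {
      fit <- try_fit(start)
      if (!is.null(fit)) break
    }
  }

  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, hill = NA_real_, amax = NA_real_,
                          baseline = if (constrain_baseline) 0 else NA_real_,
                          se = c(kd = NA, hill = NA, amax = NA,
                                 baseline = NA),
                          converged = FALSE, reliable = FALSE,
                          rss = NA_real_, data = dat,
                          ligand_nM = ligand_nM, fit = NULL),
                     class = "fp_fit"))
  }

  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(est)))
  kd <- unname(est["kd"])
  reliable <- kd >= min(x) * 0.01 && kd <= max(x) * 100
  if (!reliable) {
    warning(sprintf(
      "Kd estimate %.3g uM lies outside the testable range of this design", kd))
  }
  if (reliable && kd < 10 * ligand_nM / 1000) {
    warning("estimated Kd is within 10x the ligand concentration; ",
            "ligand depletion may bias the fit")
  }
  structure(list(kd = kd,
                 hill = unname(est["hill"]),
                 amax = unname(est["amax"]),
                 baseline = if (constrain_baseline) 0
                            else unname(est["baseline"]),
                 se = se,
                 converged = TRUE,
                 reliable = reliable,
                 rss = sum(stats::residuals(fit)^2),
                 data = dat, ligand_nM = ligand_nM, fit = fit),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("FP binding fit: did not converge\n")
    return(invisible(x))
  }
  cat("FP specific binding with Hill slope\n")
  cat(sprintf("  Kd   = %.4g uM (SE %.2g)%s\n", x$kd,
              x$se[["kd"]], if (x$reliable) "" else "  [unreliable]"))
  cat(sprintf("  Hill = %.3g (SE %.2g)\n", x$hill, x$se[["hill"]]))
  cat(sprintf("  amax = %.4g, baseline = %.4g (anisotropy units)\n",
              x$amax, x$baseline))
  cat(sprintf("  n = %d points, RSS = %.3g\n", nrow(x$data), x$rss))
  invisible(x)
}

#' @export
coef.fp_fit <- function(object, ...) {
  c(kd = object$kd, hill = object$hill, amax = object$amax,
    baseline = object$baseline)
}

#' @export
summary.fp_fit <- function(object, ...) {
  if (!object$converged) return(print(object))
  print(object)
  if (!is.null(object$fit)) print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
predict.fp_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$concentration_uM
  hill_model(x, object$kd, object$hill, object$amax, object$baseline)
}

#' @export
residuals.fp_fit <- function(object, ...) {
  object$data$A - predict(object)
}

#' @export
plot.fp_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$A, log = "x",
                 xlab = "protein (uM)", ylab = "anisotropy",
                 main = "FP titration", ...)
  if (x$converged) {
    xx <- exp(seq(log(min(x$data$x)), log(max(x$data$x)), length.out = 200))
    graphics::lines(xx, hill_model(xx, x$kd, x$hill, x$amax, x$baseline))
  }
  invisible(x)
}

#' Fold change between two dissociation constants
#'
#' `kd_b / kd_a`: a tighter binder has a smaller Kd, so a ratio above 1 means
#' the first binds tighter.
#'
#' @param kd_a,kd_b dissociation constants (same units, > 0).
#' @return Dimensionless ratio.
#' @examples
#' fold_change(0.10, 3.6) # 36
#' @export
fold_change <- function(kd_a, kd_b) {
  if (any(kd_a <= 0) || any(kd_b <= 0)) stop("Kd values must be positive")
  kd_b / kd_a
}

#' Read an FP titration table
#'
#' @param path TSV with columns `peptide_id`, `concentration_uM`, `mP`,
#'   optional `replicate`.
#' @return data.frame.
#' @export
read_titration <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("concentration_uM", "mP") %in% names(tab)))
  tab
}

#' Write a fit result as TSV and JSON
#'
#' @param fit an `fp_fit`.
#' @param stem output path stem.
#' @export
write_fit_result <- function(fit, stem) {
  tab <- data.frame(parameter = c("kd_uM", "hill", "amax", "baseline"),
                    estimate = c(fit$kd, fit$hill, fit$amax, fit$baseline),
                    se = fit$se[c("kd", "hill", "amax", "baseline")])
  utils::write.table(tab, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(kd_uM = fit$kd, hill = fit$hill, amax = fit$amax,
         baseline = fit$baseline, converged = fit$converged,
         reliable = fit$reliable, rss = fit$rss, n = nrow(fit$data)),
    paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(fit)
}
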