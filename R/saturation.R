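#' Sequencing-depth saturation analysis
#'
#' How does isoform detection degrade with depth? Reads are subsampled on a
#' fraction grid (default 5%..100% in steps of 5), the full quantification
#' is rerun per fraction, and an estimator Y is tracked against the mean
#' uniquely mapped reads per cell X. The points are then fitted with the
#' two-parameter rational model `Y = a*X / (b + X)`: `a` is the plateau
#' (theoretical maximum of the estimator) and `b` the depth at which half
#' of the plateau is reached, since `Y(b) = a/2`.
#'
#' @name saturation
NULL

#' Fraction of cells positive for a feature
#'
#' `|{cells with count > 0}| / |cells|`, computed on raw (possibly
#' fractional) counts.
#'
#' @param m count matrix (features x cells).
#' @param feature feature name.
#' @return numeric in `[0, 1]`.
#' @export
fraction_positive <- function(m, feature) {
  if (!feature %in% rownames(m)) stop("unknown feature: ", feature)
  if (ncol(m) == 0L) return(0)
  mean(m[feature, ] > 0)
}

#' Mean log-normalized count of a feature over all cells
#'
#' Mean over all cells -- zeros included -- of the per-cell log2-normalized
#' value ([log_normalize()]) for one feature.
#'
#' @param m count matrix.
#' @param feature feature name.
#' @param scale scale factor passed to [log_normalize()].
#' @return numeric scalar.
#' @export
mean_log_count <- function(m, feature, scale = 1e4) {
  if (!feature %in% rownames(m)) stop("unknown feature: ", feature)
  if (ncol(m) == 0L) return(0)
  mean(log_normalize(m, scale)[feature, ])
}

#' Default subsampling fraction grid
#'
#' 5% to 100% in increments of 5 (20 points).
#'
#' @return numeric vector of 20 fractions.
#' @export
default_fraction_grid <- function() seq(0.05, 1, by = 0.05)

#' Saturation curve by subsampling and requantification
#'
#' For every fraction: subsample the records at a fixed seed, rerun
#' classification and per-cell counting, and record the depth covariate
#' `X` ([reads_per_cell()] on the subsample) together with the estimator
#' `Y` for the given feature.
#'
#' @param records records data.frame (e.g. from [extract_locus_reads()]).
#' @param index a `feature_index`.
#' @param whitelist cell-barcode whitelist defining the cells.
#' @param feature feature to track.
#' @param fractions subsampling fractions in `(0, 1]`
#'   (default [default_fraction_grid()]).
#' @param seed subsampling seed (default 42).
#' @param estimator `"fraction_positive"` or `"mean_log_count"`.
#' @param min_kmer_frac classification threshold, see [classify_read()].
#' @param scale scale for the log normalization (mean_log_count only).
#' @return data.frame with columns `fraction`, `X`, `Y`, sorted by `X`.
#' @export
saturation_curve <- function(records, index, whitelist, feature,
                             fractions = default_fraction_grid(),
                             seed = 42L,
                             estimator = c("fraction_positive",
                                           "mean_log_count"),
                             min_kmer_frac = 0.7, scale = 1e4) {
  estimator <- match.arg(estimator)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  pts <- lapply(fractions, function(f) {
    sub <- subsample_reads(records, f, seed)
    X <- reads_per_cell(sub, whitelist)
    m <- quantify(assign_reads(sub, index, min_kmer_frac),
                  whitelist = whitelist)
    Y <- switch(estimator,
                fraction_positive = fraction_positive(m, feature),
                mean_log_count = mean_log_count(m, feature, scale))
    data.frame(fraction = f, X = X, Y = Y)
  })
  out <- do.call(rbind, pts)
  out[order(out$X), , drop = FALSE]
}

#' Fit the rational saturation model Y = a*X / (b + X)
#'
#' Nonlinear least squares with the analytic Jacobian
#' (`dY/da = X/(b+X)`, `dY/db = -a*X/(b+X)^2`), initialized at
#' `a0 = max(Y)` and `b0 = X` of the point whose `Y` is closest to `a0/2`.
#' The fit is unweighted. Success requires convergence and positive
#' parameters; on non-convergence the parameters are still returned with
#' `converged = FALSE`.
#'
#' @param points data.frame with columns `X` and `Y` (at least 3 distinct
#'   `X`, `Y` not all zero), e.g. from [saturation_curve()].
#' @return an object of class `rational_fit` with components `a` (plateau),
#'   `b` (half-saturation depth), `rss`, `converged`, `data`.
#' @examples
#' X <- seq(500, 20000, length.out = 20)
#' fit <- fit_rational(data.frame(X = X, Y = 0.8 * X / (5000 + X)))
#' coef(fit)
#' @export
fit_rational <- function(points) {
  X <- points$X; Y <- points$Y
  ok <- is.finite(X) & is.finite(Y)
  X <- X[ok]; Y <- Y[ok]
  if (length(unique(X)) < 3L) stop("need >= 3 points with distinct X")
  if (all(Y == 0)) stop("Y is identically zero; nothing to fit")
  a0 <- max(Y)
  b0 <- X[which.min(abs(Y - a0 / 2))]
  if (b0 <= 0) b0 <- stats::median(X[X > 0])
  res <- minpack.lm::nls.lm(
    par = c(a = a0, b = b0),
    fn = function(p) Y - p[1] * X / (p[2] + X),
    jac = function(p) cbind(a = -X / (p[2] + X),
                            b = p[1] * X / (p[2] + X)^2),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  a <- unname(res$par["a"]); b <- unname(res$par["b"])
  structure(list(a = a, b = b,
                 rss = sum(res$fvec^2),
                 ## info 1-3: ftol/xtol conditions; 4: gradient orthogonal
                 ## to the residual (exact on noise-free data)
                 converged = res$info %in% 1:4 && a > 0 && b > 0,
                 info = res$info,
                 data = data.frame(X = X, Y = Y)),
            class = "rational_fit")
}

#' @export
print.rational_fit <- function(x, ...) {
  cat("Rational saturation fit: Y = a*X / (b + X)\n")
  cat(sprintf("  a (plateau)          = %.6g\n", x$a))
  cat(sprintf("  b (half-max depth)   = %.6g\n", x$b))
  cat(sprintf("  RSS = %.4g over %d points; %s\n", x$rss, nrow(x$data),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.rational_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Predicted estimator values at given depths
#'
#' @param object a `rational_fit`.
#' @param newdata optional data.frame with column `X` (or numeric vector of
#'   depths); defaults to the fitted points.
#' @param ... unused.
#' @export
predict.rational_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$data$X
       else if (is.data.frame(newdata)) newdata$X else as.numeric(newdata)
  object$a * X / (object$b + X)
}

#' @export
fitted.rational_fit <- function(object, ...) predict(object)

#' @export
residuals.rational_fit <- function(object, ...)
  object$data$Y - predict(object)

#' Plot a saturation fit
#'
#' Observed points, the fitted curve, its asymptote `a` (dashed) and the
#' half-saturation depth `b` (dotted).
#'
#' @param x a `rational_fit`.
#' @param ... passed to [plot()].
#' @export
plot.rational_fit <- function(x, ...) {
  d <- x$data[order(x$data$X), ]
  plot(d$X, d$Y, xlab = "mean mapped reads per cell",
       ylab = "estimator", ...)
  xs <- seq(0, max(d$X), length.out = 200)
  graphics::lines(xs, predict(x, xs))
  graphics::abline(h = x$a, lty = 2)
  graphics::abline(v = x$b, lty = 3)
  graphics::abline(h = x$a / 2, lty = 3)
  invisible(x)
}
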