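# Box-Behnken design handling, desirability aggregation, coded-unit
# quadratic fitting, ANOVA with lack-of-fit, and constrained optimization.

#' Factor specification for a coded design
#'
#' Maps between actual units and coded units via
#' `x = (X - center) / step`, so the design levels -1/0/+1 correspond to
#' `center - step`, `center`, `center + step`.
#'
#' @param name factor name.
#' @param center center level in actual units.
#' @param step actual units per coded unit (> 0).
#' @return list of class `"factor_spec"` with `name`, `center`, `step`,
#'   `low`, `high`.
#' @export
#' @examples
#' factor_spec("liquid_solid_ratio", center = 8, step = 1)
factor_spec <- function(name, center, step) {
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  structure(list(name = as.character(name), center = center, step = step,
                 low = center - step, high = center + step),
            class = "factor_spec")
}

#' Default factor set for the two-stage water-extraction process
#'
#' First liquid-solid ratio (mL/g, center 8, step 1), first extraction
#' time (min, center 45, step 15) and second extraction time (min, center
#' 30, step 10).
#'
#' @return list of three [factor_spec()] objects.
#' @export
extraction_factors <- function() {
  list(factor_spec("first_liquid_solid_ratio", 8, 1),
       factor_spec("first_extraction_time", 45, 15),
       factor_spec("second_extraction_time", 30, 10))
}

#' Three-factor Box-Behnken design
#'
#' The 12 edge-midpoint runs (every (+/-1, +/-1) pair of two factors with
#' the third at 0) plus `n_center` center replicates; with the default 5
#' center points, 17 runs. Run order is deterministic: factor pairs in
#' order (1,2), (1,3), (2,3), levels in (-1,-1), (+1,-1), (-1,+1),
#' (+1,+1) order, centers last.
#'
#' @param factors list of exactly three [factor_spec()] objects.
#' @param n_center number of center replicates (>= 1; pure error is
#'   undefined without replication).
#' @return data frame of class `"bbd_design"` with coded columns `x1`,
#'   `x2`, `x3` and actual-unit columns named after the factors;
#'   attributes `factors` and `n_center`.
#' @export
bbd_design <- function(factors = extraction_factors(), n_center = 5) {
  if (length(factors) != 3 ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("factors must be a list of exactly 3 factor_spec objects",
         call. = FALSE)
  if (n_center < 1)
    stop("n_center must be >= 1 (pure error undefined otherwise)",
         call. = FALSE)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  lv <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  runs <- matrix(0, nrow = 0, ncol = 3)
  for (pr in pairs) {
    blk <- matrix(0, nrow = 4, ncol = 3)
    blk[, pr[1]] <- lv[, 1]
    blk[, pr[2]] <- lv[, 2]
    runs <- rbind(runs, blk)
  }
  runs <- rbind(runs, matrix(0, nrow = n_center, ncol = 3))
  colnames(runs) <- c("x1", "x2", "x3")
  actual <- sapply(seq_len(3), function(j)
    factors[[j]]$center + runs[, j] * factors[[j]]$step)
  colnames(actual) <- vapply(factors, `[[`, character(1), "name")
  out <- data.frame(run = seq_len(nrow(runs)), runs, actual,
                    check.names = FALSE)
  attr(out, "factors") <- factors
  attr(out, "n_center") <- n_center
  class(out) <- c("bbd_design", "data.frame")
  out
}

# coerce a design-like object (bbd_design or data frame with x1..x3) to
# the coded matrix
coded_matrix <- function(design) {
  need <- c("x1", "x2", "x3")
  if (!all(need %in% names(design)))
    stop("design needs coded columns x1, x2, x3", call. = FALSE)
  as.matrix(design[, need])
}

#' Linear desirability rescaling
#'
#' `d_i = (Y_i - Ymin) / (Ymax - Ymin)` for a response that is to be
#' maximized. By default the bounds are the observed minimum and maximum
#' of the response over the design (`bounds = "observed"`), so the worst
#' run scores 0 and the best 1; externally supplied bounds clip the result
#' to \[0, 1\].
#'
#' @param y response vector.
#' @param ymin,ymax supplied bounds (both or neither).
#' @return desirability vector in \[0, 1\].
#' @export
desirability <- function(y, ymin = NULL, ymax = NULL) {
  supplied <- !is.null(ymin) || !is.null(ymax)
  if (supplied && (is.null(ymin) || is.null(ymax)))
    stop("supply both ymin and ymax, or neither", call. = FALSE)
  if (!supplied) { ymin <- min(y); ymax <- max(y) }
  if (ymax <= ymin) stop("degenerate bounds: ymax must exceed ymin",
                         call. = FALSE)
  d <- (y - ymin) / (ymax - ymin)
  if (supplied) d <- pmin(pmax(d, 0), 1)
  d
}

#' Overall desirability (geometric mean)
#'
#' `OD = (d_1 d_2 ... d_n)^(1/n)` per run; zero whenever any component
#' desirability is zero.
#'
#' @param d list of equal-length desirability vectors, or a runs x
#'   responses matrix/data frame.
#' @return OD vector.
#' @export
overall_desirability <- function(d) {
  if (is.list(d) && !is.data.frame(d)) d <- do.call(cbind, d)
  d <- as.matrix(d)
  if (any(d < 0)) stop("desirabilities must be non-negative", call. = FALSE)
  apply(d, 1, function(row) prod(row)^(1 / length(row)))
}

#' Fit a full second-order model in coded units
#'
#' Ordinary least squares of the response on the ten-term coded model
#' matrix `[1, x1, x2, x3, x1 x2, x1 x3, x2 x3, x1^2, x2^2, x3^2]`.
#' On a Box-Behnken design these columns are orthogonal enough that the
#' intercept equals the mean of the center-point responses and each linear
#' coefficient equals its +/-1 contrast divided by 8.
#'
#' @param design a [bbd_design()] (or data frame with coded `x1`, `x2`,
#'   `x3`).
#' @param y response vector (e.g. the overall desirability per run).
#' @return object of class `"quadratic_model"`: `coefficients` named
#'   `b0, b1, b2, b3, b12, b13, b23, b11, b22, b33`, the underlying `lm`
#'   fit, `r_squared`, the design, and the [anova_quadratic()] table.
#' @export
fit_quadratic <- function(design, y) {
  X <- coded_matrix(design)
  if (nrow(X) != length(y))
    stop("response length does not match design", call. = FALSE)
  dat <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  fit <- stats::lm(y ~ x1 + x2 + x3 + I(x1 * x2) + I(x1 * x3) +
                     I(x2 * x3) + I(x1^2) + I(x2^2) + I(x3^2), data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient model matrix; cannot fit the full quadratic",
         call. = FALSE)
  beta <- stats::coef(fit)
  names(beta) <- c("b0", "b1", "b2", "b3", "b12", "b13", "b23",
                   "b11", "b22", "b33")
  obj <- structure(list(coefficients = beta, lm = fit, design = design,
                        r_squared = suppressWarnings(summary(fit))$r.squared,
                        residual_df = stats::df.residual(fit)),
                   class = "quadratic_model")
  obj$anova <- anova_quadratic(obj)
  obj
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat("<quadratic_model> coded-unit second-order fit\n")
  print(round(x$coefficients, 4))
  cat("R-squared:", round(x$r_squared, 4),
      " residual df:", x$residual_df, "\n")
  invisible(x)
}

# evaluate the quadratic at coded points (matrix n x 3)
eval_quadratic <- function(beta, X) {
  X <- matrix(X, ncol = 3)
  beta[["b0"]] +
    beta[["b1"]] * X[, 1] + beta[["b2"]] * X[, 2] + beta[["b3"]] * X[, 3] +
    beta[["b12"]] * X[, 1] * X[, 2] + beta[["b13"]] * X[, 1] * X[, 3] +
    beta[["b23"]] * X[, 2] * X[, 3] +
    beta[["b11"]] * X[, 1]^2 + beta[["b22"]] * X[, 2]^2 +
    beta[["b33"]] * X[, 3]^2
}

#' ANOVA for the quadratic fit, with lack-of-fit
#'
#' Partitions the total sum of squares into model and residual; the
#' residual is further split into lack-of-fit and pure error, pure error
#' being computed from the replicated runs (the center points on a
#' Box-Behnken design). Per-term F tests come from the coefficient
#' t-statistics, which on this near-orthogonal design coincide with
#' type-III tests. With a saturated (zero-residual) fit the F statistics
#' are reported as `Inf` and flagged.
#'
#' @param model a [fit_quadratic()] result.
#' @return data frame with columns `source`, `SS`, `df`, `MS`, `F`, `p`.
#' @export
anova_quadratic <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  fit <- model$lm
  dat <- fit$model
  y <- dat$y
  n <- length(y)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- n - 1 - stats::df.residual(fit)
  df_res <- stats::df.residual(fit)
  # pure error from exact replicate coded points
  key <- interaction(dat$x1, dat$x2, dat$x3, drop = TRUE)
  ss_pe <- sum(tapply(y, key, function(v) sum((v - mean(v))^2)))
  df_pe <- n - length(levels(key))
  ss_lof <- ss_res - ss_pe
  df_lof <- df_res - df_pe
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  saturated <- df_res == 0 || ss_res < 1e-12 * max(ss_tot, 1)
  f_mod <- if (saturated) Inf else (ss_mod / df_mod) / ms_res
  p_mod <- if (saturated) 0 else stats::pf(f_mod, df_mod, df_res,
                                           lower.tail = FALSE)
  rows <- data.frame(
    source = "model", SS = ss_mod, df = df_mod,
    MS = ss_mod / df_mod, F = f_mod, p = p_mod,
    stringsAsFactors = FALSE)
  # per-term tests from coefficient t statistics (summary warns on an
  # exactly interpolating fit; that case is flagged via `saturated`)
  st <- suppressWarnings(summary(fit))$coefficients
  term_names <- c("b1", "b2", "b3", "b12", "b13", "b23",
                  "b11", "b22", "b33")
  for (i in seq_along(term_names)) {
    tval <- st[i + 1, "t value"]
    rows <- rbind(rows, data.frame(
      source = term_names[i], SS = NA_real_, df = 1,
      MS = NA_real_,
      F = if (saturated) Inf else tval^2,
      p = if (saturated) 0 else st[i + 1, "Pr(>|t|)"],
      stringsAsFactors = FALSE))
  }
  rows <- rbind(rows, data.frame(source = "residual", SS = ss_res,
                                 df = df_res, MS = ms_res,
                                 F = NA_real_, p = NA_real_,
                                 stringsAsFactors = FALSE))
  if (df_pe > 0) {
    ms_pe <- ss_pe / df_pe
    if (df_lof > 0) {
      ms_lof <- ss_lof / df_lof
      f_lof <- if (ms_pe > 0) ms_lof / ms_pe else Inf
      p_lof <- if (is.finite(f_lof))
        stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE) else 0
      rows <- rbind(rows, data.frame(source = "lack_of_fit", SS = ss_lof,
                                     df = df_lof, MS = ms_lof, F = f_lof,
                                     p = p_lof, stringsAsFactors = FALSE))
    }
    rows <- rbind(rows, data.frame(source = "pure_error", SS = ss_pe,
                                   df = df_pe, MS = ms_pe, F = NA_real_,
                                   p = NA_real_, stringsAsFactors = FALSE))
  } else {
    attr(rows, "lack_of_fit_unavailable") <- TRUE
  }
  rows <- rbind(rows, data.frame(source = "total", SS = ss_tot, df = n - 1,
                                 MS = NA_real_, F = NA_real_, p = NA_real_,
                                 stringsAsFactors = FALSE))
  attr(rows, "saturated") <- saturated
  rows
}

#' Maximize the fitted quadratic over the coded cube
#'
#' Deterministic global maximization of the second-order model over
#' \[-1, 1\]^3 by exhaustive stationary-point analysis: for each of the 27
#' ways of fixing each coordinate at -1, +1 or leaving it free, the
#' stationary point of the reduced quadratic is solved analytically and
#' kept if it is feasible; the best candidate is then checked against a
#' dense grid (51 points per axis) as a safeguard. For a quadratic this
#' enumeration attains the exact constrained optimum.
#'
#' @param model a [fit_quadratic()] result.
#' @param factors list of three [factor_spec()] objects used to express
#'   the optimum in actual units; defaults to the factors attached to the
#'   model's design, else [extraction_factors()].
#' @return list of class `"rsm_optimum"`: `coded` (argmax in coded
#'   units), `actual` (named, actual units), `predicted` (model value at
#'   the argmax).
#' @export
optimize_quadratic <- function(model, factors = NULL) {
  stopifnot(inherits(model, "quadratic_model"))
  if (is.null(factors)) factors <- attr(model$design, "factors")
  if (is.null(factors)) factors <- extraction_factors()
  beta <- model$coefficients
  H <- matrix(c(2 * beta[["b11"]], beta[["b12"]], beta[["b13"]],
                beta[["b12"]], 2 * beta[["b22"]], beta[["b23"]],
                beta[["b13"]], beta[["b23"]], 2 * beta[["b33"]]),
              nrow = 3, byrow = TRUE)
  g <- c(beta[["b1"]], beta[["b2"]], beta[["b3"]])
  candidates <- list()
  fix_levels <- list(NA_real_, -1, 1)  # NA = free
  for (a in fix_levels) for (b in fix_levels) for (cc in fix_levels) {
    fx <- c(a, b, cc)
    free <- which(is.na(fx))
    x <- fx
    if (length(free)) {
      # gradient of the reduced quadratic: H[free,free] x_free +
      # (g + H[free,fixed] x_fixed) = 0
      fixed <- which(!is.na(fx))
      rhs <- -(g[free] +
                 if (length(fixed)) H[free, fixed, drop = FALSE] %*% fx[fixed]
                 else 0)
      sol <- tryCatch(solve(H[free, free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- as.numeric(sol)
      if (any(x[free] < -1 - 1e-9 | x[free] > 1 + 1e-9)) next
      x[free] <- pmin(pmax(x[free], -1), 1)
    }
    candidates[[length(candidates) + 1L]] <- x
  }
  # corners are included above (all fixed); evaluate all candidates
  cand <- do.call(rbind, candidates)
  vals <- eval_quadratic(beta, cand)
  best <- cand[which.max(vals), ]
  # dense-grid safeguard
  gr <- seq(-1, 1, length.out = 51)
  grid <- as.matrix(expand.grid(x1 = gr, x2 = gr, x3 = gr))
  gv <- eval_quadratic(beta, grid)
  if (max(gv) > max(vals) + 1e-9) best <- grid[which.max(gv), ]
  predicted <- eval_quadratic(beta, matrix(best, ncol = 3))
  actual <- vapply(seq_len(3), function(j)
    factors[[j]]$center + best[j] * factors[[j]]$step, numeric(1))
  names(actual) <- vapply(factors, `[[`, character(1), "name")
  structure(list(coded = unname(best), actual = actual,
                 predicted = as.numeric(predicted)),
            class = "rsm_optimum")
}

#' @export
print.rsm_optimum <- function(x, ...) {
  cat("<rsm_optimum> predicted response", round(x$predicted, 4), "at\n")
  print(round(x$actual, 3))
  invisible(x)
}

#' Predict from a quadratic model at actual-unit points
#'
#' Transforms actual-unit coordinates to coded units with the factor
#' specifications, then evaluates the polynomial. Points outside the
#' factor ranges are allowed but trigger a warning (extrapolation).
#'
#' @param object a [fit_quadratic()] result.
#' @param newdata numeric vector of length 3, or an n x 3 matrix/data
#'   frame, in actual units; with `coded = TRUE` the values are taken as
#'   already coded.
#' @param factors factor specifications (defaulting as in
#'   [optimize_quadratic()]).
#' @param coded whether `newdata` is already in coded units.
#' @param ... unused.
#' @return predicted response(s).
#' @export
predict.quadratic_model <- function(object, newdata, factors = NULL,
                                    coded = FALSE, ...) {
  if (is.null(factors)) factors <- attr(object$design, "factors")
  if (is.null(factors)) factors <- extraction_factors()
  X <- matrix(as.numeric(as.matrix(newdata)), ncol = 3)
  if (!coded) {
    for (j in seq_len(3))
      X[, j] <- (X[, j] - factors[[j]]$center) / factors[[j]]$step
  }
  if (any(abs(X) > 1 + 1e-9))
    warning("prediction outside the design region (coded |x| > 1)")
  eval_quadratic(object$coefficients, X)
}

#' Prediction grid over a factor pair, for contour/surface plots
#'
#' @param model a [fit_quadratic()] result.
#' @param pair indices of the two varying factors (e.g. `c(1, 2)`).
#' @param fixed_level coded level of the remaining factor (default 0).
#' @param n grid points per axis.
#' @param factors factor specifications (defaulting as in
#'   [optimize_quadratic()]).
#' @return data frame with the two factors' actual-unit coordinates and
#'   the `predicted` response.
#' @export
surface_grid <- function(model, pair = c(1, 2), fixed_level = 0, n = 41,
                         factors = NULL) {
  stopifnot(inherits(model, "quadratic_model"),
            length(pair) == 2, all(pair %in% 1:3), pair[1] != pair[2])
  if (is.null(factors)) factors <- attr(model$design, "factors")
  if (is.null(factors)) factors <- extraction_factors()
  gr <- seq(-1, 1, length.out = n)
  other <- setdiff(1:3, pair)
  grid <- expand.grid(a = gr, b = gr)
  X <- matrix(fixed_level, nrow = nrow(grid), ncol = 3)
  X[, pair[1]] <- grid$a
  X[, pair[2]] <- grid$b
  out <- data.frame(
    v1 = factors[[pair[1]]]$center + grid$a * factors[[pair[1]]]$step,
    v2 = factors[[pair[2]]]$center + grid$b * factors[[pair[2]]]$step,
    predicted = eval_quadratic(model$coefficients, X))
  names(out)[1:2] <- vapply(factors[pair], `[[`, character(1), "name")
  attr(out, "fixed_factor") <- factors[[other]]$name
  attr(out, "fixed_level") <- fixed_level
  out
}
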