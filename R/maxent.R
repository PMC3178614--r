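#' Fit an L1-regularized maximum-entropy distribution model
#'
#' Estimates the presence-only maximum-entropy model: the exponential
#' distribution over background cells
#' \deqn{q(x) = e^{\eta(x)} / Z, \quad \eta(x) = \sum_j \lambda_j f_j(x)}
#' whose weights minimize the convex objective
#' \deqn{-\frac{1}{m}\sum_{i \in presence} \eta(x_i) + \log Z
#'       + \sum_j \beta_j |\lambda_j|.}
#' Optimization is coordinate-wise proximal Newton (a 1-D Newton step on the
#' smooth part followed by soft-thresholding), with step halving so the
#' objective decreases monotonically across accepted iterations. The fit is
#' deterministic given its inputs.
#'
#' Per-feature regularization follows the class-specific default tables of
#' the standard maxent implementation, interpolated by presence sample size
#' and scaled by `reg_multiplier`:
#' \eqn{\beta_j = reg\_multiplier \cdot \beta_{class}(m) \cdot
#'      \max(s_j, 0.05)/\sqrt{m}}
#' with \eqn{s_j} the standard deviation of feature j over the presences.
#' Passing `beta` overrides the table with an explicit per-feature (or
#' scalar) regularization amount.
#'
#' @param presence_cells integer grid cell ids of presences (>= 1).
#' @param background_cells integer grid cell ids of the background. The
#'   presence cells are always added to the background (standard
#'   presence-only convention).
#' @param features a [expand_features()] result covering all these cells.
#' @param reg_multiplier scales all regularization amounts (default 1).
#' @param tol convergence tolerance on relative objective change
#'   (default 1e-5).
#' @param max_iter maximum coordinate sweeps (default 500).
#' @param beta optional explicit regularization: scalar or one value per
#'   feature; bypasses the default tables.
#' @return a `maxent_model`: weights `lambda`, regularization `beta`,
#'   entropy `H` of the fitted distribution over the background, the
#'   background cell ids, objective trace, and convergence info.
#' @export
fit_maxent <- function(presence_cells, background_cells, features,
                       reg_multiplier = 1.0, tol = 1e-5, max_iter = 500L,
                       beta = NULL) {
  if (length(presence_cells) < 1) stop("no presence cells")
  bg_cells <- sort(unique(c(background_cells, presence_cells)))
  ip <- feature_rows(features, presence_cells)
  ib <- feature_rows(features, bg_cells)
  Fp <- features$M[ip, , drop = FALSE]
  Fb <- features$M[ib, , drop = FALSE]
  if (any(!is.finite(Fp)) || any(!is.finite(Fb)))
    stop("non-finite feature values")
  m <- length(presence_cells)
  p <- ncol(Fb)
  beta_j <- if (!is.null(beta)) rep_len(beta, p)
  else default_beta(features$descriptors, Fp, m) * reg_multiplier

  pres_mean <- if (p) colMeans(Fp) else numeric(0)
  lambda <- numeric(p)
  eta <- rep(0, nrow(Fb))
  obj_of <- function(eta, lambda) {
    M <- max(eta)
    -sum(pres_mean * lambda) + M + log(sum(exp(eta - M))) +
      sum(beta_j * abs(lambda))
  }
  obj <- obj_of(eta, lambda)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter && p > 0) {
    iter <- iter + 1L
    obj_prev <- obj
    M <- max(eta)
    w <- exp(eta - M); w <- w / sum(w)   # current q over background
    for (j in seq_len(p)) {
      fj <- Fb[, j]
      Eq <- sum(w * fj)
      Vq <- sum(w * fj * fj) - Eq^2
      g <- Eq - pres_mean[j]             # gradient of smooth part
      h <- max(Vq, 1e-8)
      target <- lambda[j] - g / h
      new_l <- sign(target) * max(0, abs(target) - beta_j[j] / h)
      d <- new_l - lambda[j]
      if (d == 0) next
      # step-halving safeguard on the full objective
      repeat {
        eta_try <- eta + d * fj
        o_try <- obj_of(eta_try, replace(lambda, j, lambda[j] + d))
        if (o_try <= obj + 1e-12 || abs(d) < 1e-12) break
        d <- d / 2
      }
      if (abs(d) >= 1e-12) {
        lambda[j] <- lambda[j] + d
        eta <- eta + d * fj
        M <- max(eta)
        w <- exp(eta - M); w <- w / sum(w)
        obj <- obj_of(eta, lambda)
      }
    }
    trace <- c(trace, obj)
    if (abs(obj_prev - obj) <= tol * (abs(obj_prev) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (p == 0) converged <- TRUE
  M <- max(eta)
  q <- exp(eta - M); q <- q / sum(q)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  structure(list(lambda = lambda, beta = beta_j,
                 feature_names = colnames(features$M),
                 descriptors = features$descriptors,
                 background_cells = bg_cells,
                 presence_cells = presence_cells,
                 H = H, entropy = H, objective = obj,
                 objective_trace = trace,
                 converged = converged, n_iter = iter,
                 tau = 0.5),
            class = "maxent_model")
}

# class-specific default regularization tables (interpolated by sample size)
default_beta <- function(descriptors, Fp, m) {
  interp <- function(sizes, betas) stats::approx(
    sizes, betas, xout = min(max(m, sizes[1]), sizes[length(sizes)]),
    rule = 2)$y
  b_lqp <- interp(c(0, 10, 30, 100), c(1.0, 1.0, 0.2, 0.05))
  b_cat <- interp(c(0, 10, 17), c(0.65, 0.5, 0.25))
  b_thr <- interp(c(0, 100), c(2.0, 1.0))
  b_hin <- 0.5
  cls <- descriptors$class
  base <- ifelse(cls %in% c("linear", "quadratic", "product"), b_lqp,
          ifelse(cls == "category", b_cat,
          ifelse(cls %in% c("hinge", "hinge_reverse"), b_hin, b_thr)))
  s <- if (nrow(Fp) > 1) apply(Fp, 2, stats::sd) else rep(0, ncol(Fp))
  base * pmax(s, 0.05) / sqrt(m)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features, %d non-zero weights, H = %.4f, %s after %d sweeps\n",
    length(x$lambda), sum(x$lambda != 0), x$H,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Predict a suitability surface from a fitted maxent model
#'
#' The raw output is the fitted exponential distribution normalized over the
#' model's background cells (it sums to 1 there); cells outside the
#' background share the same normalizing constant. The logistic output maps
#' raw values onto \[0,1\] via \eqn{L(x) = c\,q(x)/(1 + c\,q(x))} with
#' \eqn{c = e^H}, the convention that assigns suitability 0.5 to a cell of
#' typical (entropy-level) raw probability (prevalence \eqn{\tau = 0.5}).
#'
#' @param object a `maxent_model`.
#' @param features the [expand_features()] matrix used in fitting (same
#'   descriptors).
#' @param ... unused.
#' @return a `suitability_surface`: per-grid-cell `raw` and `logistic`
#'   vectors (`NA` outside the stack's valid cells) plus provenance fields.
#' @export
predict.maxent_model <- function(object, features, ...) {
  if (!identical(object$feature_names, colnames(features$M)))
    stop("feature descriptors do not match the fitted model")
  eta <- as.numeric(features$M %*% object$lambda)
  ib <- feature_rows(features, object$background_cells)
  Mx <- max(eta[ib])
  Z <- sum(exp(eta[ib] - Mx))
  raw_valid <- exp(eta - Mx) / Z
  c_H <- exp(object$H)
  logistic_valid <- c_H * raw_valid / (1 + c_H * raw_valid)
  n <- n_cells(features$grid)
  raw <- rep(NA_real_, n); lgt <- rep(NA_real_, n)
  raw[features$cell_ids] <- raw_valid
  lgt[features$cell_ids] <- logistic_valid
  structure(list(grid = features$grid, raw = raw, logistic = lgt,
                 background_cells = object$background_cells,
                 H = object$H),
            class = "suitability_surface")
}

#' Logistic transform of raw maxent output
#'
#' @param raw raw (normalized exponential) values.
#' @param H entropy of the raw distribution over the background.
#' @return logistic suitability in \[0,1\].
#' @export
raw_to_logistic <- function(raw, H) {
  c_H <- exp(H)
  c_H * raw / (1 + c_H * raw)
}
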