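# Rigid-body pose optimization and the three similarity scores.
#
# The pose of molecule B relative to a fixed molecule A is parameterized by
# a quaternion (normalized inside every evaluation) plus a translation.
# Objectives are maximized by BFGS with an analytic gradient over
# precomputed pair constants, started from four deterministic
# inertial-frame orientations.

# Pose-independent constants of one Gaussian-set pair: the weighted
# prefactor matrix and the exponent-rate matrix. Only the pair distances
# change during optimization, so these are computed once per pair.
pair_ctx <- function(ga, gb) {
  asum <- outer(ga$alpha, gb$alpha, "+")
  list(
    ca = ga$centers, cb = gb$centers,
    ra2 = rowSums(ga$centers^2),
    coef = outer(ga$weights * ga$p, gb$weights * gb$p) * (pi / asum)^1.5,
    kmat = outer(ga$alpha, gb$alpha) / asum
  )
}

# Weighted overlap (and analytic gradient) of a precomputed pair context
# under theta = c(q, t): quaternion (normalized internally, gradient via
# the projection Jacobian) then translation.
ctx_eval <- function(ctx, theta, grad = FALSE) {
  q <- theta[1:4]; tv <- theta[5:7]
  qn <- sqrt(sum(q^2))
  qh <- q / qn
  R <- quat_to_matrix(qh)
  bp <- ctx$cb %*% t(R)
  bp[, 1] <- bp[, 1] + tv[1]; bp[, 2] <- bp[, 2] + tv[2]
  bp[, 3] <- bp[, 3] + tv[3]
  d2 <- outer(ctx$ra2, rowSums(bp^2), "+") - 2 * (ctx$ca %*% t(bp))
  karg <- ctx$kmat * d2
  E <- exp(-karg)
  E[karg > 27.6] <- 0
  W <- ctx$coef * E
  value <- sum(W)
  if (!grad) return(list(value = value))
  M <- 2 * W * ctx$kmat
  colsM <- colSums(M)
  Gj <- crossprod(M, ctx$ca) - bp * colsM
  dt <- colSums(Gj)
  D <- quat_matrix_derivs(qh)
  dqh <- vapply(D, function(Dm) sum(Gj * (ctx$cb %*% t(Dm))), numeric(1))
  J <- (diag(4) - tcrossprod(qh)) / qn
  list(value = value, grad = c(as.numeric(J %*% dqh), dt))
}

# One-off evaluation without a cached context.
gauss_overlap_core <- function(ga, gb, theta, grad = FALSE, cutoff = TRUE) {
  ctx_eval(pair_ctx(ga, gb), theta, grad = grad)
}

#' Gradient of the molecular overlap with respect to pose parameters
#'
#' Analytic gradient of \eqn{O_{AB}} under a rigid transform of B,
#' with respect to the quaternion components and the translation.
#'
#' @param A,B `shape_model` objects.
#' @param transform A [rigid_transform()] applied to B.
#' @return List with `value` (the overlap) and `grad` (length 7:
#'   quaternion then translation).
#' @export
overlap_gradient <- function(A, B, transform = rigid_transform()) {
  gauss_overlap_core(A, B, c(transform$q, transform$t), grad = TRUE)
}

# Per-type pair contexts for two feature models.
feature_ctxs <- function(F_A, F_B) {
  types <- intersect(names(F_A$by_type), names(F_B$by_type))
  lapply(stats::setNames(types, types), function(ty) {
    pair_ctx(F_A$by_type[[ty]], F_B$by_type[[ty]])
  })
}

ctxs_eval <- function(ctxs, theta, grad = FALSE) {
  value <- 0
  g <- numeric(7)
  for (ctx in ctxs) {
    r <- ctx_eval(ctx, theta, grad = grad)
    value <- value + r$value
    if (grad) g <- g + r$grad
  }
  if (grad) list(value = value, grad = g) else list(value = value)
}

# Feature-overlap value/gradient under theta (sum over shared types).
feature_overlap_core <- function(F_A, F_B, theta, grad = FALSE) {
  ctxs_eval(feature_ctxs(F_A, F_B), theta, grad = grad)
}

#' Shape Tanimoto similarity at a pose
#'
#' \eqn{T = O_{AB} / (O_{AA} + O_{BB} - O_{AB})}, clamped to \[0, 1\].
#'
#' @param A,B `shape_model` objects.
#' @param transform [rigid_transform()] applied to B.
#' @return Similarity in \[0, 1\].
#' @export
shape_tanimoto <- function(A, B, transform = rigid_transform()) {
  if (A$self_overlap <= 0 || B$self_overlap <= 0) {
    stop("degenerate shape model: zero self-overlap")
  }
  oab <- gauss_overlap_core(A, B, c(transform$q, transform$t))$value
  min(max(oab / (A$self_overlap + B$self_overlap - oab), 0), 1)
}

#' Feature Tanimoto similarity at a pose
#'
#' Same Tanimoto form on same-type pharmacophore feature overlaps; `NA`
#' when either molecule is featureless.
#'
#' @param F_A,F_B `feature_model` objects.
#' @param transform [rigid_transform()] applied to `F_B`.
#' @return Similarity in \[0, 1\], or `NA`.
#' @export
feature_tanimoto <- function(F_A, F_B, transform = rigid_transform()) {
  if (n_features(F_A) == 0L || n_features(F_B) == 0L) return(NA_real_)
  fab <- feature_overlap_core(F_A, F_B, c(transform$q, transform$t))$value
  denom <- F_A$self_overlap + F_B$self_overlap - fab
  if (denom <= 0) return(1)
  min(max(fab / denom, 0), 1)
}

# Weighted-volume centroid and principal axes (eigenvectors of the second
# moment of the weighted density), det fixed to +1.
principal_frame <- function(model) {
  mass <- model$weights * model$hard_volume
  mu <- colSums(model$centers * mass) / sum(mass)
  X <- sweep(model$centers, 2, mu)
  Mom <- t(X) %*% (X * mass) / sum(mass)
  ev <- eigen(Mom, symmetric = TRUE)
  E <- ev$vectors
  if (det(E) < 0) E[, 3] <- -E[, 3]
  list(mu = mu, axes = E)
}

#' Deterministic inertial starting orientations
#'
#' Centers B on A's weighted-volume centroid and aligns B's principal axes
#' to A's; returns the four proper-rotation sign combinations (identity and
#' 180 degrees about each principal axis). Single-atom molecules get a
#' translation-only start.
#'
#' @param A,B `shape_model` objects.
#' @return List of [rigid_transform()] starts for B.
#' @export
initial_orientations <- function(A, B) {
  fa <- principal_frame(A)
  fb <- principal_frame(B)
  if (nrow(A$centers) == 1L || nrow(B$centers) == 1L) {
    return(list(rigid_transform(t = fa$mu - fb$mu)))
  }
  flips <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
                diag(c(-1, -1, 1)))
  lapply(flips, function(S) {
    R <- fa$axes %*% S %*% t(fb$axes)
    rigid_transform(q = matrix_to_quat(R), t = fa$mu - as.numeric(R %*% fb$mu))
  })
}

# Maximize the pose objective over theta = c(q, t) by BFGS with the
# analytic gradient (monotone line search: only improving steps are
# accepted). Function and gradient at the same point share one evaluation
# through a small memo.
ascend_pose <- function(objective, start, max_iter = 200L, tol = 1e-6) {
  theta0 <- c(start$q, start$t)
  memo <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (!is.null(memo$th) && identical(memo$th, th) && !is.null(memo$res$grad)) {
      return(memo$res)
    }
    res <- objective(th, grad = TRUE)
    memo$th <- th
    memo$res <- res
    res
  }
  f0 <- objective(theta0)$value
  fit <- tryCatch(
    stats::optim(theta0,
                 fn = function(th) -eval_at(th)$value,
                 gr = function(th) -eval_at(th)$grad,
                 method = "BFGS",
                 control = list(maxit = max_iter, reltol = tol * 1e-2)),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par)) || -fit$value < f0) {
    # fall back to the start if the search failed or did not improve
    return(list(transform = start, objective = f0, iterations = 0L,
                converged = TRUE))
  }
  theta <- fit$par
  theta[1:4] <- theta[1:4] / sqrt(sum(theta[1:4]^2))
  list(transform = rigid_transform(theta[1:4], theta[5:7]),
       objective = -fit$value,
       iterations = unname(fit$counts[1]),
       converged = fit$convergence == 0L)
}

similarity_result <- function(shape, feature, mode, transform,
                              conformer_a, conformer_b, start = NA_integer_,
                              iterations = NA_integer_, converged = NA) {
  combo <- if (is.na(feature)) shape else (shape + feature) / 2
  score <- switch(mode, shape = shape, feature = feature, combo = combo)
  structure(list(
    shape_tanimoto = shape, feature_tanimoto = feature, combo = combo,
    score = score, mode = mode, transform = transform,
    conformer_a = conformer_a, conformer_b = conformer_b,
    start = start, iterations = iterations, converged = converged
  ), class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result mode=%s score=%.4f (shape=%.4f feature=%s) conformers %d/%d>\n",
    x$mode, x$score, x$shape_tanimoto,
    if (is.na(x$feature_tanimoto)) "NA" else sprintf("%.4f", x$feature_tanimoto),
    x$conformer_a, x$conformer_b))
  invisible(x)
}

# Build the mode objective for one conformer pair. Shape: O_AB. Feature:
# feature overlap. Combo: each overlap normalized by the mean of the two
# self-overlaps so neither term's scale dominates.
make_objective <- function(A, B, F_A, F_B, mode) {
  if (mode == "shape") {
    ctx <- pair_ctx(A, B)
    function(theta, grad = FALSE) ctx_eval(ctx, theta, grad = grad)
  } else if (mode == "feature") {
    ctxs <- feature_ctxs(F_A, F_B)
    function(theta, grad = FALSE) ctxs_eval(ctxs, theta, grad = grad)
  } else {
    ctx <- pair_ctx(A, B)
    ms <- (A$self_overlap + B$self_overlap) / 2
    featureless <- is.null(F_A) || is.null(F_B) ||
      n_features(F_A) == 0L || n_features(F_B) == 0L
    mf <- if (featureless) 1 else (F_A$self_overlap + F_B$self_overlap) / 2
    ctxs <- if (featureless) list() else feature_ctxs(F_A, F_B)
    function(theta, grad = FALSE) {
      rs <- ctx_eval(ctx, theta, grad = grad)
      if (featureless) {
        rs$value <- rs$value / ms
        if (grad) rs$grad <- rs$grad / ms
        return(rs)
      }
      rf <- ctxs_eval(ctxs, theta, grad = grad)
      out <- list(value = rs$value / ms + rf$value / mf)
      if (grad) out$grad <- rs$grad / ms + rf$grad / mf
      out
    }
  }
}

#' Optimize the pose of B against a fixed A from one start
#'
#' Local gradient-based (BFGS) maximization of the mode objective over
#' rotation and translation; the line search only accepts improving steps,
#' so the objective is non-decreasing across iterations, and the search
#' stops once relative gains fall below `tol` (default 1e-6) or after
#' `max_iter` iterations. A failed or non-improving search returns the
#' start pose unchanged.
#'
#' @param A,B `shape_model` objects (B is moved).
#' @param F_A,F_B `feature_model` objects (required for feature/combo).
#' @param mode `"shape"`, `"feature"` or `"combo"`.
#' @param start A [rigid_transform()] start for B.
#' @param max_iter,tol Convergence controls.
#' @return A `similarity_result` scored at the optimized pose.
#' @export
optimize_alignment <- function(A, B, F_A = NULL, F_B = NULL,
                               mode = c("shape", "feature", "combo"),
                               start = rigid_transform(),
                               max_iter = 200L, tol = 1e-6) {
  mode <- match.arg(mode)
  if (mode %in% c("feature", "combo") && (is.null(F_A) || is.null(F_B))) {
    if (mode == "feature") stop("feature mode requires feature models")
  }
  if (mode == "feature") {
    if (n_features(F_A) == 0L) stop("feature mode: molecule A has no features")
    if (n_features(F_B) == 0L) stop("feature mode: molecule B has no features")
  }
  obj <- make_objective(A, B, F_A, F_B, mode)
  fit <- ascend_pose(obj, start, max_iter = max_iter, tol = tol)
  st <- shape_tanimoto(A, B, fit$transform)
  ft <- if (is.null(F_A) || is.null(F_B)) NA_real_ else
    feature_tanimoto(F_A, F_B, fit$transform)
  similarity_result(st, ft, mode, fit$transform, NA_integer_, NA_integer_,
                    iterations = fit$iterations, converged = fit$converged)
}

prepare_conformer_models <- function(mol, params = shape_params(),
                                     rules = default_feature_rules(),
                                     features = TRUE) {
  nc <- n_conformers(mol)
  list(
    shape = lapply(seq_len(nc), make_shape_model, mol = mol, params = params),
    feature = if (features)
      lapply(seq_len(nc), assign_features, mol = mol, rules = rules,
             p = params$p)
    else NULL
  )
}

#' Align two molecules and return the best similarity
#'
#' Runs [optimize_alignment()] over all conformer pairs and all inertial
#' starts (plus optional seeded random extra starts) and returns the best
#' result by the mode's score. Ties below 1e-9 go to the lower conformer
#' indices, then to the earlier start.
#'
#' @param molA Fixed molecule (template frame is preserved).
#' @param molB Moving molecule.
#' @param mode `"shape"`, `"feature"` or `"combo"`.
#' @param params [shape_params()].
#' @param rules Feature ruleset.
#' @param extra_starts Number of additional random-rotation starts (uses
#'   the current RNG stream; seed upstream for determinism).
#' @param models_a,models_b Optional precomputed model caches from
#'   `prepare_conformer_models()` (used by database scans).
#' @param max_iter,tol Convergence controls.
#' @return The winning `similarity_result`; `conformer_a`/`conformer_b`
#'   name the winning conformers and `transform` maps `molB` onto `molA`'s
#'   frame.
#' @export
align_and_score <- function(molA, molB, mode = c("shape", "feature", "combo"),
                            params = shape_params(),
                            rules = default_feature_rules(),
                            extra_starts = 0L,
                            models_a = NULL, models_b = NULL,
                            max_iter = 200L, tol = 1e-6) {
  mode <- match.arg(mode)
  need_feat <- mode %in% c("feature", "combo")
  if (is.null(models_a)) {
    models_a <- prepare_conformer_models(molA, params, rules, features = need_feat)
  }
  if (is.null(models_b)) {
    models_b <- prepare_conformer_models(molB, params, rules, features = need_feat)
  }
  if (mode == "feature") {
    if (all(vapply(models_a$feature, n_features, integer(1)) == 0L)) {
      stop("feature mode: molecule '", molA$id, "' has no pharmacophore features")
    }
    if (all(vapply(models_b$feature, n_features, integer(1)) == 0L)) {
      stop("feature mode: molecule '", molB$id, "' has no pharmacophore features")
    }
  }
  extra <- if (extra_starts > 0L) {
    lapply(seq_len(extra_starts), function(i) random_rigid_transform(0))
  } else list()
  best <- NULL
  for (ia in seq_along(models_a$shape)) {
    A <- models_a$shape[[ia]]
    F_A <- if (need_feat) models_a$feature[[ia]] else NULL
    for (ib in seq_along(models_b$shape)) {
      B <- models_b$shape[[ib]]
      F_B <- if (need_feat) models_b$feature[[ib]] else NULL
      if (mode == "feature" &&
          (n_features(F_A) == 0L || n_features(F_B) == 0L)) next
      starts <- c(initial_orientations(A, B), extra)
      for (is in seq_along(starts)) {
        res <- optimize_alignment(A, B, F_A, F_B, mode, start = starts[[is]],
                                  max_iter = max_iter, tol = tol)
        res$conformer_a <- ia
        res$conformer_b <- ib
        res$start <- is
        if (is.null(best) || res$score > best$score + 1e-9) best <- res
      }
    }
  }
  if (is.null(best)) {
    stop("no scorable conformer pair between '", molA$id, "' and '",
         molB$id, "'")
  }
  best
}
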