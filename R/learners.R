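#' @title Learner registry and envelope-model fitting
#' @description Single-species models are fitted through a pluggable learner
#'   contract: a learner is registered under a name with a `fit(spec, X, y)`
#'   function returning opaque artifacts and a `predict(artifacts, X)`
#'   function returning probabilities in `[0, 1]`. Two learners ship with
#'   the package: `"glm_poly2"`, a ridge-stabilised logistic regression on
#'   linear plus quadratic terms of every predictor; `"glm_lin"`, the same
#'   with linear terms only (a monotone response surface that extrapolates
#'   very differently); `"cta"`, a classification tree (via \pkg{rpart});
#'   and `"sre"`, a surface range envelope on presence-only quantiles.
#'   Together they span the smooth/monotone/piecewise-constant/envelope
#'   behaviours of the classical ensemble-SDM algorithm families. Any
#'   number of additional learners can be plugged in via
#'   [register_learner].
#' @name learner-registry
NULL

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner
#'
#' @param name Learner name used in [learner_spec].
#' @param fit Function `(spec, X, y)` where `X` is the numeric predictor
#'   matrix (training cells x predictors, named columns) and `y` a 0/1
#'   vector; returns arbitrary fit artifacts.
#' @param predict Function `(artifacts, X)` returning per-row probabilities
#'   in `[0, 1]`.
#' @return Invisibly, `name`.
#' @export
register_learner <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  assign(name, list(fit = fit, predict = predict), envir = .learner_registry)
  invisible(name)
}

#' List registered learner names
#' @return Character vector.
#' @export
registered_learners <- function() sort(ls(.learner_registry))

get_learner <- function(name) {
  if (!exists(name, envir = .learner_registry, inherits = FALSE)) {
    stop("unknown learner '", name, "'; registered: ",
         paste(registered_learners(), collapse = ", "))
  }
  get(name, envir = .learner_registry, inherits = FALSE)
}

#' Specification of one ensemble member
#'
#' @param name Registered learner name (e.g. `"glm_poly2"`, `"sre"`).
#' @param hyperparameters Named list of learner hyperparameters.
#' @param seed Optional seed for stochastic learners.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(name, hyperparameters = list(), seed = NULL) {
  get_learner(name)  # validates registration
  structure(list(name = name, hyperparameters = hyperparameters, seed = seed),
            class = "learner_spec")
}

# ---- ridge logistic (IRLS) ------------------------------------------------
# Penalised Fisher scoring on standardised columns; the tiny default ridge
# (1e-6) keeps perfectly separable fits finite without visibly biasing
# estimates. Covariance from the penalised information, back-transformed to
# the raw predictor scale.

fit_ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L,
                               tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  mu_x <- colMeans(X)
  sd_x <- apply(X, 2L, stats::sd)
  sd_x[sd_x == 0] <- 1
  Xs <- cbind(`(Intercept)` = 1, sweep(sweep(X, 2L, mu_x), 2L, sd_x, "/"))
  pen <- diag(c(0, rep(lambda, p)), p + 1L)
  beta <- c(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)), rep(0, p))
  for (it in seq_len(max_iter)) {
    eta <- drop(Xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    H <- crossprod(Xs, Xs * w) + pen
    beta_new <- tryCatch(drop(solve(H, crossprod(Xs, w * z))),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(Xs %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  H <- crossprod(Xs, Xs * w) + pen
  vcov_std <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, p + 1L, p + 1L)
  })
  # back-transform: beta_raw_j = beta_std_j / sd_j;
  # intercept_raw = b0 - sum(beta_std_j * mean_j / sd_j)
  Tm <- diag(c(1, 1 / sd_x), p + 1L)
  Tm[1L, -1L] <- -mu_x / sd_x
  beta_raw <- drop(Tm %*% beta)
  vcov_raw <- Tm %*% vcov_std %*% t(Tm)
  names(beta_raw) <- c("(Intercept)", colnames(X))
  dimnames(vcov_raw) <- list(names(beta_raw), names(beta_raw))
  list(beta_std = beta, mu_x = mu_x, sd_x = sd_x,
       coefficients = beta_raw, vcov = vcov_raw)
}

predict_ridge_logistic <- function(fit, X) {
  Xs <- cbind(1, sweep(sweep(X, 2L, fit$mu_x), 2L, fit$sd_x, "/"))
  stats::plogis(drop(Xs %*% fit$beta_std))
}

# glm_poly2: logistic regression on v + v^2 per predictor, zero-variance
# predictors dropped with a warning.
glm_poly2_fit <- function(spec, X, y) {
  lambda <- spec$hyperparameters$ridge %||% 1e-6
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("glm_poly2: dropping zero-variance predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("glm_poly2: no non-degenerate predictors left")
  P <- poly2_design(X)
  fit <- fit_ridge_logistic(P, y, lambda = lambda)
  list(fit = fit, vars = colnames(X))
}

poly2_design <- function(X) {
  P <- cbind(X, X^2)
  colnames(P) <- c(colnames(X), paste0("I(", colnames(X), "^2)"))
  P
}

glm_poly2_predict <- function(artifacts, X) {
  predict_ridge_logistic(artifacts$fit,
                         poly2_design(X[, artifacts$vars, drop = FALSE]))
}

# glm_lin: logistic regression on linear terms only.
glm_lin_fit <- function(spec, X, y) {
  lambda <- spec$hyperparameters$ridge %||% 1e-6
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("glm_lin: dropping zero-variance predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("glm_lin: no non-degenerate predictors left")
  list(fit = fit_ridge_logistic(X, y, lambda = lambda), vars = colnames(X))
}

glm_lin_predict <- function(artifacts, X) {
  predict_ridge_logistic(artifacts$fit, X[, artifacts$vars, drop = FALSE])
}

# cta: classification tree analysis (rpart), probabilities from leaves.
cta_fit <- function(spec, X, y) {
  cp <- spec$hyperparameters$cp %||% 0.01
  minbucket <- spec$hyperparameters$minbucket %||% 7L
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  df$.y <- factor(y, levels = c(0L, 1L))
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = cp,
                                                     minbucket = minbucket,
                                                     xval = 0L))
  list(fit = fit, vars = colnames(X))
}

cta_predict <- function(artifacts, X) {
  df <- as.data.frame(X[, artifacts$vars, drop = FALSE])
  names(df) <- make.names(artifacts$vars)
  unname(stats::predict(artifacts$fit, df, type = "prob")[, "1"])
}

# sre: surface range envelope on [q, 1-q] presence-only quantiles.
sre_fit <- function(spec, X, y) {
  q <- spec$hyperparameters$quantile %||% 0.025
  if (q < 0 || q >= 0.5) stop("sre quantile must be in [0, 0.5)")
  pres <- X[y == 1, , drop = FALSE]
  if (nrow(pres) < 2L) stop("sre requires at least 2 presences")
  bounds <- apply(pres, 2L, stats::quantile, probs = c(q, 1 - q),
                  names = FALSE, type = 7)
  list(lo = bounds[1L, ], hi = bounds[2L, ], vars = colnames(X))
}

sre_predict <- function(artifacts, X) {
  X <- X[, artifacts$vars, drop = FALSE]
  inside <- rep(TRUE, nrow(X))
  for (j in seq_along(artifacts$vars)) {
    inside <- inside & X[, j] >= artifacts$lo[j] & X[, j] <= artifacts$hi[j]
  }
  as.numeric(inside)
}

register_builtin_learners <- function() {
  register_learner("glm_poly2", glm_poly2_fit, glm_poly2_predict)
  register_learner("glm_lin", glm_lin_fit, glm_lin_predict)
  register_learner("cta", cta_fit, cta_predict)
  register_learner("sre", sre_fit, sre_predict)
}
# registered at package load and immediately so sourced use also works
register_builtin_learners()

.onLoad <- function(libname, pkgname) register_builtin_learners()

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- data split -----------------------------------------------------------

#' One-time random train/test split of surveyed cells
#'
#' Seeded uniform partition (unstratified) of all surveyed cells into
#' `round(fraction * n)` training cells and the rest as test cells.
#'
#' @param occurrence An [occurrence_map]; only cells with known status are
#'   partitioned.
#' @param fraction Training fraction, default 0.7.
#' @param seed Integer RNG seed.
#' @return An object of class `data_split`: list with `training` and `test`
#'   cell-id vectors, `fraction`, `seed` and `empty_test` flag.
#' @export
split_data <- function(occurrence, fraction = 0.7, seed = 1L) {
  stopifnot(inherits(occurrence, "occurrence_map"),
            fraction > 0, fraction <= 1)
  surveyed <- occurrence$grid$cell_ids[occurrence$status != "unknown"]
  st <- occurrence$status[occurrence$status != "unknown"]
  if (!any(st == "present") || !any(st == "absent")) {
    stop("split_data requires both presences and absences among surveyed cells")
  }
  n <- length(surveyed)
  n_train <- round(fraction * n)
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  empty_test <- n_train == n
  if (empty_test) warning("fraction 1.0 leaves an empty test set")
  structure(list(training = surveyed[train],
                 test = surveyed[setdiff(seq_len(n), train)],
                 fraction = fraction, seed = seed, empty_test = empty_test),
            class = "data_split")
}

# ---- predictor assembly ---------------------------------------------------

# Matrix of predictors over all cells (NA rows where masked); extra
# suitability maps are appended as ordinary predictors.
predictor_matrix <- function(layers, extra_predictors = NULL) {
  stopifnot(inherits(layers, "climate_layers"))
  cols <- layers$variables
  if (!is.null(extra_predictors)) {
    if (is.null(names(extra_predictors)) ||
        any(!nzchar(names(extra_predictors)))) {
      stop("extra_predictors must be a named list of suitability maps")
    }
    for (nm in names(extra_predictors)) {
      s <- extra_predictors[[nm]]
      stopifnot(inherits(s, "suitability_map"))
      assert_aligned(layers, s)
      cols[[nm]] <- s$probability
    }
  }
  do.call(cbind, cols)
}

#' Fit a single learner
#'
#' @param spec A [learner_spec].
#' @param layers Predictor [climate_layers].
#' @param occurrence Response [occurrence_map] for one species.
#' @param cells Training cell ids (must have known status and complete
#'   predictors).
#' @param extra_predictors Optional named list of [suitability_map]s to
#'   append as additional predictors (the explanatory-variable scheme).
#' @return An object of class `fitted_learner`.
#' @export
fit_learner <- function(spec, layers, occurrence, cells,
                        extra_predictors = NULL) {
  stopifnot(inherits(spec, "learner_spec"))
  assert_aligned(layers, occurrence)
  M <- predictor_matrix(layers, extra_predictors)
  idx <- match(cells, layers$grid$cell_ids)
  if (anyNA(idx)) stop("unknown training cell id(s)")
  st <- occurrence$status[idx]
  complete <- stats::complete.cases(M[idx, , drop = FALSE]) & st != "unknown"
  idx <- idx[complete]
  st <- st[complete]
  if (!length(idx)) stop("no usable training cells")
  y <- as.integer(st == "present")
  lrn <- get_learner(spec$name)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  artifacts <- lrn$fit(spec, M[idx, , drop = FALSE], y)
  structure(list(spec = spec, predictors = colnames(M),
                 artifacts = artifacts,
                 n_presences = sum(y), n_absences = sum(1 - y)),
            class = "fitted_learner")
}

#' Raw-scale coefficients of a fitted glm_poly2 learner
#' @param object A `fitted_learner` with spec name `"glm_poly2"`.
#' @param ... Unused.
#' @return Named numeric coefficient vector on the raw predictor scale.
#' @export
coef.fitted_learner <- function(object, ...) {
  if (object$spec$name != "glm_poly2") {
    stop("coefficients only available for glm_poly2 learners")
  }
  object$artifacts$fit$coefficients
}

#' Coefficient covariance of a fitted glm_poly2 learner
#' @param object A `fitted_learner` with spec name `"glm_poly2"`.
#' @param ... Unused.
#' @return Covariance matrix on the raw predictor scale.
#' @export
vcov.fitted_learner <- function(object, ...) {
  if (object$spec$name != "glm_poly2") {
    stop("vcov only available for glm_poly2 learners")
  }
  object$artifacts$fit$vcov
}

#' Fit an ensemble of learners
#'
#' Members are fitted independently on the same training cells; predictions
#' are combined by the probability mean (the arithmetic mean of member
#' probabilities).
#'
#' @inheritParams fit_learner
#' @param specs List of [learner_spec]s (at least one).
#' @return An object of class `ensemble_model`.
#' @export
fit_ensemble <- function(specs, layers, occurrence, cells,
                         extra_predictors = NULL) {
  stopifnot(length(specs) >= 1L)
  members <- lapply(specs, fit_learner, layers = layers,
                    occurrence = occurrence, cells = cells,
                    extra_predictors = extra_predictors)
  structure(list(members = members, combination = "probability_mean",
                 member_auc = NULL),
            class = "ensemble_model")
}

predict_matrix_learner <- function(model, M) {
  p <- rep(NA_real_, nrow(M))
  ok <- stats::complete.cases(M)
  if (any(ok)) {
    lrn <- get_learner(model$spec$name)
    p[ok] <- lrn$predict(model$artifacts, M[ok, , drop = FALSE])
  }
  pmin(pmax(p, 0), 1)
}

predict_matrix <- function(model, M) {
  if (inherits(model, "fitted_learner")) return(predict_matrix_learner(model, M))
  if (inherits(model, "ensemble_model")) {
    ps <- vapply(model$members, predict_matrix_learner, numeric(nrow(M)),
                 M = M)
    return(rowMeans(matrix(ps, nrow = nrow(M))))
  }
  stop("not a fitted model")
}

#' Predict occurrence probability over a grid
#'
#' @param model A `fitted_learner` or `ensemble_model`.
#' @param layers Predictor [climate_layers] containing all predictor names.
#' @param extra_predictors Optional named list of [suitability_map]s, as at
#'   fit time.
#' @param species Species label for the output map.
#' @return A [suitability_map] (ensembles: probability mean of members;
#'   missing cells propagate as NA).
#' @export
predict_prob <- function(model, layers, extra_predictors = NULL,
                         species = "modelled") {
  M <- predictor_matrix(layers, extra_predictors)
  needed <- if (inherits(model, "ensemble_model")) {
    unique(unlist(lapply(model$members, `[[`, "predictors")))
  } else model$predictors
  missing_vars <- setdiff(needed, colnames(M))
  if (length(missing_vars)) {
    stop("missing predictor(s): ", paste(missing_vars, collapse = ", "))
  }
  src <- if (inherits(model, "ensemble_model")) {
    paste0("ensemble(", paste(vapply(model$members,
                                     function(m) m$spec$name, ""),
                              collapse = "+"), ")")
  } else model$spec$name
  suitability_map(layers$grid, species, layers$period,
                  predict_matrix(model, M), source = src)
}

# ---- permutation variable importance --------------------------------------

cor_or_zero <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Permutation importance of each predictor variable
#'
#' For each variable, its values are permuted across (non-missing) cells
#' `n_perm` times and the model re-applied; importance is the mean of
#' `1 - cor(reference predictions, permuted predictions)`. A permutation
#' that flattens predictions to a constant has destroyed all signal, so the
#' correlation with a constant vector is defined as 0 (importance 1).
#' Variables not among the model's predictors score exactly 0. For
#' ensembles the importance is computed on the combined (probability-mean)
#' predictions, not averaged over members.
#'
#' @param model A `fitted_learner` or `ensemble_model`.
#' @param layers Predictor [climate_layers].
#' @param n_perm Number of permutations per variable (>= 1).
#' @param seed Integer RNG seed.
#' @param extra_predictors Optional named list of [suitability_map]s.
#' @return Named numeric vector of importances (order: predictor columns).
#' @export
variable_importance <- function(model, layers, n_perm = 10L, seed = 1L,
                                extra_predictors = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  M <- predictor_matrix(layers, extra_predictors)
  ok <- stats::complete.cases(M)
  M <- M[ok, , drop = FALSE]
  ref <- predict_matrix(model, M)
  used_of <- function(m) m$artifacts$vars %||% m$predictors
  used <- if (inherits(model, "ensemble_model")) {
    unique(unlist(lapply(model$members, used_of)))
  } else {
    used_of(model)
  }
  set.seed(seed)
  imp <- stats::setNames(numeric(ncol(M)), colnames(M))
  for (v in colnames(M)) {
    if (!(v %in% used)) { imp[[v]] <- 0; next }
    vals <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      Mp <- M
      Mp[, v] <- M[sample.int(nrow(M)), v]
      vals[k] <- 1 - cor_or_zero(ref, predict_matrix(model, Mp))
    }
    imp[[v]] <- mean(vals)
  }
  imp
}

#' Rank variables by importance
#'
#' Descending importance; ties broken lexicographically by variable name.
#'
#' @param importances Named numeric vector as returned by
#'   [variable_importance].
#' @return Character vector of variable names, most important first.
#' @export
rank_variables <- function(importances) {
  if (!length(importances) || is.null(names(importances))) {
    stop("importances must be a non-empty named vector")
  }
  names(importances)[order(-importances, names(importances))]
}
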