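#' Factorial table of projection outcomes
#'
#' One relative-change value per (algorithm, approach) combination, from
#' approach runs re-fitted per individual learner (no ensemble averaging),
#' so the table isolates algorithmic and scheme-related variation.
#'
#' @param results Nested named list: `results[[algorithm]][[approach]]` is
#'   an `approach_result` (or a [binary_range_map] of the future range).
#' @param current_observed Observed current [occurrence_map].
#' @return An object of class `projection_outcome_table` (a data.frame with
#'   columns algorithm, approach, relative_change).
#' @export
build_outcome_table <- function(results, current_observed) {
  algs <- names(results)
  if (is.null(algs) || !length(algs)) stop("results must be a named list")
  approaches <- names(results[[1L]])
  rows <- list()
  for (a in algs) {
    for (ap in approaches) {
      r <- results[[a]][[ap]]
      if (is.null(r)) stop("missing combination: ", a, " x ", ap)
      fut <- if (inherits(r, "binary_range_map")) r else r$binary$future
      s <- range_change(current_observed, fut)
      rows[[length(rows) + 1L]] <-
        data.frame(algorithm = a, approach = ap,
                   relative_change = s$relative_change)
    }
    extra <- setdiff(names(results[[a]]), approaches)
    if (length(extra)) {
      stop("incomplete factorial: algorithm ", a,
           " has extra approach(es): ", paste(extra, collapse = ", "))
    }
    if (!setequal(names(results[[a]]), approaches)) {
      stop("incomplete factorial: algorithm ", a, " is missing approach(es): ",
           paste(setdiff(approaches, names(results[[a]])), collapse = ", "))
    }
  }
  structure(do.call(rbind, rows),
            class = c("projection_outcome_table", "data.frame"))
}

r_squared <- function(y, X) {
  if (is.null(X) || !ncol(X)) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - rss / tss
}

factor_design <- function(df, fac) {
  f <- factor(df[[fac]])
  if (nlevels(f) < 2L) {
    stop("factor '", fac, "' has fewer than 2 levels")
  }
  stats::model.matrix(~f)[, -1L, drop = FALSE]
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Hierarchical partitioning of projection variance
#'
#' Attributes the variance of a projection outcome (default: relative range
#' change) to categorical uncertainty factors (default: modelling algorithm
#' and interaction approach) by all-subsets regression on a Gaussian linear
#' model with R-squared as goodness of fit. The independent contribution
#' `I_k` of factor `k` is the average, over all orderings of the factors,
#' of the R-squared increase when `k` enters the model; for two factors
#' `I_A = [R2(A) + R2(A,B) - R2(B)] / 2`. The joint contribution is
#' `J_k = R2(k) - I_k`. Shares are normalised over independent
#' contributions to sum to 100 percent; small negative `I_k` are possible
#' and reported as-is.
#'
#' @param table A `projection_outcome_table` (or any data.frame with the
#'   response and factor columns).
#' @param response Response column name.
#' @param factors Character vector of factor column names (each >= 2
#'   levels).
#' @return An object of class `variance_partition`: data.frame `partition`
#'   (factor, independent, joint, share_pct) and scalar `r2_full`.
#' @export
hierarchical_partition <- function(table, response = "relative_change",
                                   factors = c("algorithm", "approach")) {
  df <- as.data.frame(table)
  stopifnot(response %in% names(df), all(factors %in% names(df)),
            length(factors) >= 1L)
  y <- df[[response]]
  designs <- lapply(factors, factor_design, df = df)
  names(designs) <- factors
  subset_r2 <- function(subset) {
    if (!length(subset)) return(0)
    r_squared(y, do.call(cbind, designs[subset]))
  }
  # cache R^2 for every subset of factors
  subsets <- unlist(lapply(0:length(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  key <- function(s) paste0("{", paste(sort(s), collapse = "|"), "}")
  r2 <- stats::setNames(vapply(subsets, subset_r2, 0),
                        vapply(subsets, key, ""))
  perms <- all_permutations(factors)
  indep <- stats::setNames(numeric(length(factors)), factors)
  for (perm in perms) {
    before <- character(0)
    for (f in perm) {
      indep[[f]] <- indep[[f]] +
        (r2[[key(c(before, f))]] - r2[[key(before)]]) / length(perms)
      before <- c(before, f)
    }
  }
  joint <- vapply(factors, function(f) r2[[key(f)]] - indep[[f]], 0)
  total_i <- sum(indep)
  share <- if (total_i != 0) 100 * indep / total_i else indep * NA_real_
  structure(list(partition = data.frame(factor = factors,
                                        independent = unname(indep),
                                        joint = unname(joint),
                                        share_pct = unname(share)),
                 r2_full = r2[[key(factors)]]),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("<variance_partition> R2(full) =", round(x$r2_full, 4), "\n")
  print(x$partition, row.names = FALSE)
  invisible(x)
}
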