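resolve_vars <- function(fm, subset) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (is.numeric(subset)) {
    idx <- as.integer(subset)
  } else {
    s <- as.character(subset)
    idx <- match(s, fm$catalog$index)
    idx[is.na(idx)] <- match(s[is.na(idx)], fm$catalog$label)
    if (anyNA(idx))
      stop("unknown variable(s): ", paste(s[is.na(idx)], collapse = ", "))
  }
  if (any(idx < 1 | idx > ncol(fm$values)))
    stop("variable index out of range 1..", ncol(fm$values))
  if (anyDuplicated(idx)) stop("duplicate variables in subset")
  sort(idx)
}

# In-fit R^2 of one k-subset; the GA fitness kernel. sstot precomputed by
# the caller; zero response variance maps to R^2 = 0 by convention.
r2_subset <- function(X, y, idx, sstot) {
  if (sstot == 0) return(0)
  f <- .lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sstot
}

#' Ordinary least squares on a variable subset
#'
#' Fits `I% ~ intercept + sum_j beta_j V_j` over the selected bond-length
#' columns. Reports the in-fit determination coefficient
#' `R^2 = 1 - SS_res/SS_tot` and the in-fit root-mean-square error in I%
#' units (no validation split: the model is descriptive, computed in
#' fitting). A zero-variance response yields `R^2 = 0` by convention.
#'
#' @param fm a `FeatureMatrix`.
#' @param subset variables to use: integer indices, `"Vj"` labels, or
#'   rendered residue labels (`"Trp74"`, `"WSer73"`).
#' @return an `MLRFit`: `intercept`, named `coefficients`, `variables`
#'   (catalog rows used), `r_squared`, `rmse`, named `predictions`,
#'   `residuals`.
#' @export
fit_mlr <- function(fm, subset) {
  idx <- resolve_vars(fm, subset)
  y <- fm$response
  n <- length(y)
  if (n < length(idx) + 2)
    stop("need at least ", length(idx) + 2, " rows to fit ", length(idx),
         " variables with an intercept; have ", n)
  X <- fm$values[, idx, drop = FALSE]
  labels <- fm$catalog$label[idx]
  Z <- cbind(`(Intercept)` = 1, X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qz, y)
  pred <- drop(Z %*% beta)
  res <- y - pred
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum(res^2) / sstot
  names(pred) <- names(res) <- fm$row_ids
  coefs <- beta[-1]
  names(coefs) <- labels
  structure(list(intercept = unname(beta[1]), coefficients = coefs,
                 variables = fm$catalog[idx, , drop = FALSE],
                 r_squared = r2, rmse = sqrt(mean(res^2)),
                 predictions = pred, residuals = res, n = n),
            class = "MLRFit")
}

#' @export
print.MLRFit <- function(x, ...) {
  cat(sprintf("MLRFit: %d variables, n = %d, R^2 = %.3f, RMSE = %.2f I%%\n",
              length(x$coefficients), x$n, x$r_squared, x$rmse))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 3))
  invisible(x)
}

new_subset_selection <- function(idx, fm, fit, method, extra = list()) {
  structure(c(list(variable_indices = idx,
                   variables = fm$catalog$index[idx],
                   labels = fm$catalog$label[idx],
                   fitness = fit$r_squared,
                   fit = fit,
                   method = method),
              extra),
            class = "SubsetSelection")
}

#' @export
print.SubsetSelection <- function(x, ...) {
  cat(sprintf("SubsetSelection (%s): {%s} fitness R^2 = %.4f\n",
              x$method, paste(x$variables, collapse = ", "), x$fitness))
  invisible(x)
}

#' Exhaustive fixed-size subset search
#'
#' Evaluates every k-subset of variables by OLS and returns the one with
#' maximal in-fit R^2 (exact ties resolved in favour of the
#' lexicographically first subset). Serves as the ground-truth oracle for
#' [ga_select()] on small instances.
#'
#' @param fm a `FeatureMatrix`.
#' @param k subset cardinality.
#' @param max_combinations enumeration cap on `choose(p, k)`.
#' @return a `SubsetSelection`.
#' @export
exhaustive_select <- function(fm, k, max_combinations = 5e5) {
  p <- ncol(fm$values)
  if (k < 1 || k > p) stop("k must lie in 1..", p)
  if (choose(p, k) > max_combinations)
    stop("choose(", p, ", ", k, ") exceeds the enumeration cap (",
         format(max_combinations, scientific = FALSE),
         "); use ga_select() instead")
  X <- fm$values; y <- fm$response
  sstot <- sum((y - mean(y))^2)
  combos <- utils::combn(p, k)
  fitness <- apply(combos, 2, function(idx) r2_subset(X, y, idx, sstot))
  best <- which.max(fitness)   # first maximum = lexicographically first
  idx <- combos[, best]
  new_subset_selection(idx, fm, fit_mlr(fm, idx), "exhaustive")
}

#' Genetic algorithm configuration
#'
#' @param k subset cardinality (the number of regression variables;
#'   default 8, about a quarter of a 31-variable catalog — more overfits,
#'   fewer correlates weakly).
#' @param population_size individuals per generation (default 100).
#' @param generations number of generations (default 200).
#' @param mutation_rate per-individual probability of one swap mutation.
#' @param elitism_count best individuals copied unchanged (default 1).
#' @param tournament_size parents drawn per tournament (default 3).
#' @param seed RNG seed; every run is bit-reproducible given the seed.
#' @return a `GAConfig` list.
#' @export
ga_config <- function(k = 8, population_size = 100, generations = 200,
                      mutation_rate = 0.1, elitism_count = 1,
                      tournament_size = 3, seed = 1) {
  stopifnot(k >= 1, population_size >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0, elitism_count < population_size,
            tournament_size >= 1)
  structure(list(k = as.integer(k),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "GAConfig")
}

#' Genetic-algorithm subset selection with OLS R^2 fitness
#'
#' Searches fixed-cardinality variable subsets for the multiple linear
#' regression of I% on bond lengths. Individuals are k-subsets; fitness is
#' the in-fit determination coefficient of the OLS fit. Each generation
#' applies tournament selection, cardinality-preserving uniform crossover
#' (union of the parents, repaired to size k by random subsampling), swap
#' mutation (one selected variable replaced by an unselected one with
#' probability `mutation_rate`), and elitism. The best individual ever
#' evaluated is returned with its full fit and the per-generation
#' population-best fitness trace (non-decreasing under elitism).
#'
#' @param fm a `FeatureMatrix` with no missing cells.
#' @param config a `GAConfig`, see [ga_config()].
#' @return a `SubsetSelection` with a `trace` element.
#' @export
ga_select <- function(fm, config = ga_config()) {
  stopifnot(inherits(config, "GAConfig"))
  X <- fm$values; y <- fm$response
  p <- ncol(X); k <- config$k
  if (k > p) stop("k = ", k, " exceeds the number of variables p = ", p)
  if (any(!is.finite(X))) stop("feature matrix has missing cells")
  sstot <- sum((y - mean(y))^2)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  fitness_of <- function(idx) {
    key <- paste(idx, collapse = ",")
    f <- cache[[key]]
    if (is.null(f)) {
      f <- r2_subset(X, y, idx, sstot)
      cache[[key]] <- f
    }
    f
  }
  tournament <- function(fit) {
    cand <- sample.int(length(fit), config$tournament_size, replace = TRUE)
    cand[which.max(fit[cand])]
  }

  best_idx <- NULL; best_fit <- -Inf
  trace <- numeric(config$generations)
  withr::with_seed(config$seed, {
    pop <- replicate(config$population_size, sort(sample.int(p, k)),
                     simplify = FALSE)
    for (g in seq_len(config$generations)) {
      fit <- vapply(pop, fitness_of, numeric(1))
      o <- order(fit, decreasing = TRUE)
      if (fit[o[1]] > best_fit) {
        best_fit <- fit[o[1]]
        best_idx <- pop[[o[1]]]
      }
      trace[g] <- fit[o[1]]
      if (g == config$generations) break
      elite <- pop[o[seq_len(config$elitism_count)]]
      n_child <- config$population_size - config$elitism_count
      children <- vector("list", n_child)
      for (i in seq_len(n_child)) {
        u <- union(pop[[tournament(fit)]], pop[[tournament(fit)]])
        child <- if (length(u) == k) u else u[sample.int(length(u), k)]
        if (stats::runif(1) < config$mutation_rate) {
          pool <- setdiff(seq_len(p), child)
          if (length(pool) > 0)
            child[sample.int(k, 1)] <- pool[sample.int(length(pool), 1)]
        }
        children[[i]] <- sort(child)
      }
      pop <- c(elite, children)
    }
  })
  new_subset_selection(best_idx, fm, fit_mlr(fm, best_idx), "ga",
                       extra = list(trace = trace, config = config))
}

#' Coefficient-sign interpretation report
#'
#' Maps each fitted coefficient to its sign and the mechanistic reading
#' used for bond-length variables: a negative coefficient means the bond
#' must be as short as possible (a strong hydrogen bond favours activity);
#' a positive coefficient means the bond should be as long as possible,
#' i.e. the ligand must not interact with that residue. Bridged variables
#' are rendered with the `W` prefix.
#'
#' @param fit an `MLRFit`.
#' @return a `SignReport` data frame: `variable`, `label`, `coefficient`,
#'   `sign` (`"+"`, `"-"`, `"0"`), `interpretation`.
#' @export
sign_report <- function(fit) {
  stopifnot(inherits(fit, "MLRFit"))
  s <- sign(fit$coefficients)
  out <- data.frame(
    variable = fit$variables$index,
    label = fit$variables$label,
    coefficient = unname(fit$coefficients),
    sign = c(`-1` = "-", `0` = "0", `1` = "+")[as.character(s)],
    interpretation = c(`-1` = "short-bond-favors-activity",
                       `0` = "none",
                       `1` = "no-interaction-favors-activity")[as.character(s)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("SignReport", "data.frame")
  out
}
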