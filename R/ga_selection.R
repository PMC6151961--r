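#' GA configuration for descriptor subset selection
#'
#' @param crossover_fraction fraction of each new generation produced by
#'   crossover, in (0, 1].
#' @param mutation_rate per-gene bit-flip probability, in (0, 1].
#' @param n_select_min,n_select_max cardinality bounds on the selected
#'   descriptor subset (defaults 5 and 20).
#' @param selection_fn parent selection: `"uniform"`, `"roulette"` or
#'   `"tournament"`.
#' @param crossover_fn `"scattered"` (uniform mask), `"single_point"` or
#'   `"two_point"`.
#' @param population_size,generations GA size controls.
#' @param seed integer seed; every stochastic step derives from it.
#' @param cv_folds folds used to pick the per-subset number of latent
#'   variables (default 7).
#' @param A_max cap on latent variables considered per subset.
#' @param local_search refine the final GA subset by first-improvement
#'   local search over single-descriptor swaps, drops and adds until a
#'   local optimum (default TRUE); the memetic step is cheap because
#'   fitness values are cached.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(crossover_fraction = 0.8, mutation_rate = 0.2,
                      n_select_min = 5, n_select_max = 20,
                      selection_fn = c("tournament", "uniform", "roulette"),
                      crossover_fn = c("scattered", "single_point",
                                       "two_point"),
                      population_size = 64, generations = 100, seed = 1,
                      cv_folds = 7, A_max = 7, local_search = TRUE) {
  selection_fn <- match.arg(selection_fn)
  crossover_fn <- match.arg(crossover_fn)
  stopifnot(crossover_fraction > 0, crossover_fraction <= 1,
            mutation_rate > 0, mutation_rate <= 1,
            n_select_min >= 1, n_select_max >= n_select_min,
            population_size >= 2, generations >= 1)
  structure(list(crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate,
                 n_select_min = n_select_min, n_select_max = n_select_max,
                 selection_fn = selection_fn, crossover_fn = crossover_fn,
                 population_size = population_size,
                 generations = generations, seed = seed,
                 cv_folds = cv_folds, A_max = A_max,
                 local_search = local_search),
            class = "ga_config")
}

#' Pooled weighted RMSE per response
#'
#' The per-response component of the subset-selection fitness:
#' `eta_j = sqrt(((n_T - n_S - 1) RMSEE_j^2 + n_P RMSEP_j^2) /
#' (n_T + n_P - n_S - 1))`.
#'
#' @param rmsee,rmsep per-response errors (vectors of equal length).
#' @param n_T,n_P,n_S training size, validation size, subset size.
#' @return vector of pooled errors, one per response.
#' @export
eta_pooled <- function(rmsee, rmsep, n_T, n_P, n_S) {
  if (n_T + n_P - n_S - 1 <= 0) stop("non-positive pooled degrees of freedom")
  sqrt(((n_T - n_S - 1) * rmsee^2 + n_P * rmsep^2) / (n_T + n_P - n_S - 1))
}

#' Subset-selection fitness (pooled weighted RMSE)
#'
#' Fits a PLS model on the given descriptor subset (number of latent
#' variables chosen by k-fold cross-validation on the training set) and
#' scores it with the composite error
#' \deqn{\eta_j = \sqrt{\frac{(n_T - n_S - 1)\,\mathrm{RMSEE}_j^2 +
#'   n_P\,\mathrm{RMSEP}_j^2}{n_T + n_P - n_S - 1}}, \qquad
#'   \eta = \sqrt{\eta_1^2 + \eta_2^2}}
#' where \eqn{n_T}, \eqn{n_P} and \eqn{n_S} are the numbers of training
#' samples, external validation samples and selected descriptors.  The
#' weighting penalizes complex subsets (large \eqn{n_S}) and pools the
#' training and prediction errors on a common degrees-of-freedom scale.
#'
#' @param subset character vector of descriptor names (or integer indices).
#' @param X_train,Y_train,X_test,Y_test aligned raw-unit data.
#' @param cv_folds,A_max,cv_seed latent-variable selection controls.
#' @return list with `eta`, `eta1`, `eta2`, per-response `rmsee`/`rmsep`,
#'   and `A_chosen`.
#' @export
ga_fitness <- function(subset, X_train, Y_train, X_test, Y_test,
                       cv_folds = 7, A_max = 7, cv_seed = 1) {
  if (!length(subset)) stop("empty descriptor subset")
  Xtr <- X_train[, subset, drop = FALSE]
  Xte <- X_test[, subset, drop = FALSE]
  n_T <- nrow(Xtr); n_P <- nrow(Xte); n_S <- ncol(Xtr)
  if (n_T - n_S - 1 < 0)
    stop("subset larger than the training set allows (n_T - n_S - 1 < 0)")
  cv <- cross_validate(Xtr, Y_train, A_max = min(A_max, n_S),
                       k = cv_folds, seed = cv_seed)
  model <- fit_pls(Xtr, Y_train, A = cv$A_chosen)
  met <- pls_metrics(model, Xtr, Y_train, Xte, Y_test)
  eta_j <- eta_pooled(met$rmsee, met$rmsep, n_T, n_P, n_S)
  list(eta = sqrt(sum(eta_j^2)), eta1 = unname(eta_j[1]),
       eta2 = unname(eta_j[2]),
       rmsee = met$rmsee, rmsep = met$rmsep, A_chosen = cv$A_chosen)
}

# repair a logical chromosome into the cardinality window [lo, hi]
repair_cardinality <- function(mask, lo, hi) {
  k <- sum(mask)
  if (k < lo) {
    off <- which(!mask)
    mask[off[sample.int(length(off), lo - k)]] <- TRUE
  } else if (k > hi) {
    on <- which(mask)
    mask[on[sample.int(length(on), k - hi)]] <- FALSE
  }
  mask
}

#' Genetic-algorithm descriptor subset selection
#'
#' Binary-membership chromosomes over the filtered descriptor pool are
#' evolved to minimize [ga_fitness()].  Offspring cardinality is repaired by
#' random add/drop into `[n_select_min, n_select_max]`, the single best
#' individual is carried over unchanged (elitism), and the whole run is
#' reproducible from `config$seed`.  Fitness values are cached per subset,
#' so revisited chromosomes cost nothing.
#'
#' @param X_train,Y_train,X_test,Y_test aligned raw-unit data (descriptor
#'   columns must be named).
#' @param config a [ga_config()].
#' @return object of class `selection_result` with `selected_names`, `eta`,
#'   `eta1`, `eta2`, `rmsee`, `rmsep`, `A_chosen` and `history` (best eta
#'   per generation).
#' @export
run_ga <- function(X_train, Y_train, X_test, Y_test, config = ga_config()) {
  p <- ncol(X_train)
  nm <- colnames(X_train)
  if (is.null(nm)) stop("descriptor columns must be named")
  lo <- config$n_select_min
  hi <- min(config$n_select_max, p, nrow(X_train) - 2)
  if (lo > hi) stop("infeasible cardinality bounds: [", lo, ", ", hi, "]")
  npop <- config$population_size
  cache <- new.env(parent = emptyenv())
  evaluate <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- ga_fitness(nm[mask], X_train, Y_train, X_test, Y_test,
                      cv_folds = config$cv_folds, A_max = config$A_max,
                      cv_seed = config$seed)
    cache[[key]] <- fit
    fit
  }
  local_seed(config$seed, {
    pop <- lapply(seq_len(npop), function(i) {
      k <- sample(seq(lo, hi), 1)
      mask <- rep(FALSE, p)
      mask[sample.int(p, k)] <- TRUE
      mask
    })
    fits <- lapply(pop, evaluate)
    etas <- vapply(fits, `[[`, numeric(1), "eta")
    history <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      parents_of <- switch(config$selection_fn,
        uniform = function() sample.int(npop, 2),
        roulette = function() {
          w <- max(etas) - etas + 1e-12   # minimization: invert on rank scale
          sample.int(npop, 2, prob = w / sum(w))
        },
        tournament = function() {
          c1 <- sample.int(npop, 2); c2 <- sample.int(npop, 2)
          c(c1[which.min(etas[c1])], c2[which.min(etas[c2])])
        })
      cross <- switch(config$crossover_fn,
        scattered = function(a, b) {
          m <- stats::runif(p) < 0.5
          ifelse(m, a, b)
        },
        single_point = function(a, b) {
          cut <- sample.int(p - 1, 1)
          c(a[seq_len(cut)], b[(cut + 1):p])
        },
        two_point = function(a, b) {
          cuts <- sort(sample.int(p - 1, 2))
          out <- a
          out[(cuts[1] + 1):cuts[2]] <- b[(cuts[1] + 1):cuts[2]]
          out
        })
      elite <- which.min(etas)
      children <- vector("list", npop)
      children[[1]] <- pop[[elite]]
      for (i in 2:npop) {
        if (stats::runif(1) < config$crossover_fraction) {
          pr <- parents_of()
          child <- cross(pop[[pr[1]]], pop[[pr[2]]])
        } else {
          child <- pop[[sample.int(npop, 1)]]
        }
        child <- repair_cardinality(child, lo, hi)
        # cardinality-preserving swap mutation: each selected gene is
        # exchanged with a random unselected one with prob mutation_rate
        k <- sum(child)
        nswap <- stats::rbinom(1, k, config$mutation_rate)
        if (nswap > 0 && k < p) {
          on <- which(child); off <- which(!child)
          drop_ <- on[sample.int(length(on), min(nswap, length(on)))]
          add_ <- off[sample.int(length(off), length(drop_))]
          child[drop_] <- FALSE; child[add_] <- TRUE
        }
        children[[i]] <- child
      }
      pop <- children
      fits <- lapply(pop, evaluate)
      etas <- vapply(fits, `[[`, numeric(1), "eta")
      history[gen] <- min(etas)
    }
    best <- which.min(etas)
    best_mask <- pop[[best]]
    best_eta <- etas[best]
    if (isTRUE(config$local_search)) {
      # memetic refinement: first-improvement over swap/drop/add moves
      for (pass in 1:25) {
        on <- which(best_mask); off <- which(!best_mask)
        moves <- rbind(
          if (length(on) > lo) cbind(on, 0L),                 # drops
          if (length(on) < hi) cbind(0L, off),                # adds
          as.matrix(expand.grid(on, off)))                    # swaps
        improved <- FALSE
        for (mi in seq_len(nrow(moves))) {
          cand <- best_mask
          if (moves[mi, 1] > 0) cand[moves[mi, 1]] <- FALSE
          if (moves[mi, 2] > 0) cand[moves[mi, 2]] <- TRUE
          fe <- evaluate(cand)$eta
          if (fe < best_eta - 1e-12) {
            best_mask <- cand; best_eta <- fe; improved <- TRUE
            break
          }
        }
        if (!improved) break
      }
    }
    bf <- evaluate(best_mask)
    structure(list(selected_names = nm[best_mask],
                   eta = bf$eta, eta1 = bf$eta1, eta2 = bf$eta2,
                   rmsee = bf$rmsee, rmsep = bf$rmsep,
                   A_chosen = bf$A_chosen,
                   history = cummin(history),
                   config = config),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result:", length(x$selected_names), "descriptors,",
      x$A_chosen, "latent variables, eta =", signif(x$eta, 5), "\n")
  cat("  ", paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}

#' Grid search over GA hyper-parameters
#'
#' Exhaustively evaluates [run_ga()] over the cross product of the supplied
#' hyper-parameter values (by convention crossover fraction and mutation
#' rate on the grid 0.2, 0.4, 0.6, 0.8, plus the selection and crossover
#' operator enums).  Each cell runs with its own seed derived from
#' `base_config$seed` plus the cell index.
#'
#' @param X_train,Y_train,X_test,Y_test aligned raw-unit data.
#' @param grid named list of vectors over `ga_config` fields, e.g.
#'   `list(crossover_fraction = c(0.2, 0.4), selection_fn = "tournament")`.
#' @param base_config defaults for fields not in the grid.
#' @return data.frame of configurations with their best `eta` and selected
#'   subset (comma-joined), sorted by `eta`; the full `selection_result`s
#'   are attached as the `"results"` attribute.
#' @export
ga_grid_search <- function(X_train, Y_train, X_test, Y_test,
                           grid, base_config = ga_config()) {
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- base_config
    for (f in names(cells)) cfg[[f]] <- cells[[f]][i]
    cfg$seed <- base_config$seed + i
    results[[i]] <- run_ga(X_train, Y_train, X_test, Y_test, cfg)
  }
  out <- cells
  out$eta <- vapply(results, `[[`, numeric(1), "eta")
  out$n_selected <- vapply(results, function(r) length(r$selected_names),
                           integer(1))
  out$selected <- vapply(results, function(r)
    paste(r$selected_names, collapse = ","), character(1))
  ord <- order(out$eta)
  out <- out[ord, , drop = FALSE]
  attr(out, "results") <- results[ord]
  out
}
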