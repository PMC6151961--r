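#' Build a constrained model-inversion problem
#'
#' Sets up the optimization that inverts a fitted PLS model toward
#' reference drug properties: minimize
#' `(logkw_hat - logkw_ref)^2 + (logKi_hat - logKi_ref)^2` over descriptor
#' vectors `x`, subject to the candidate staying inside the model's valid
#' region.  Two quadratic constraints define that region:
#' `t' S^-1 t <= c1` (Hotelling T-squared of the candidate's scores within
#' the F-based critical ellipsoid) and a reconstruction-residual bound
#' `||x_s - P t||^2 <= c2` derived from the critical DModX through the
#' training normalization `c2 = s0^2 (p - A) dmodx_crit^2`.  Box bounds
#' come from the training min/max per descriptor; integer and binary
#' descriptors are restricted to their lattices.
#'
#' @param model a `pls_model`.
#' @param reference a [reference_properties()].
#' @param train_X raw-unit training descriptor matrix (for the bounds).
#' @param kinds per-descriptor kind vector; defaults to all continuous.
#' @param alpha significance level for both critical limits (default 0.05).
#' @param squared_residual compare the squared residual norm against `c2`
#'   (default TRUE); FALSE uses the unsquared norm.
#' @param ga a [inversion_ga_config()].
#' @return object of class `inversion_problem`.
#' @export
build_inversion_problem <- function(model, reference, train_X,
                                    kinds = NULL, alpha = 0.05,
                                    squared_residual = TRUE,
                                    ga = inversion_ga_config()) {
  if (is.null(model$score_cov)) stop("model lacks a score covariance")
  train_X <- as.matrix(train_X)
  p <- model$p; A <- model$A; n <- model$n_train
  if (is.null(kinds)) kinds <- rep("continuous", p)
  if (length(kinds) != p) stop("kinds length must equal p")
  c1 <- t2_critical(A, n, alpha)
  s0_sq <- model$ssx_residual / ((n - A - 1) * (p - A))
  c2 <- s0_sq * (p - A) * dmodx_critical(model, alpha)^2
  if (A < 2)
    warning("fewer latent variables than responses: the inversion is ",
            "rank-deficient and admits a continuum of equivalent solutions")
  structure(list(model = model, reference = reference,
                 bounds = list(lower = apply(train_X, 2, min),
                               upper = apply(train_X, 2, max)),
                 kinds = kinds, c1 = c1, c2 = c2, alpha = alpha,
                 squared_residual = squared_residual,
                 train_X = train_X, ga = ga),
            class = "inversion_problem")
}

#' GA settings for the model inversion
#'
#' Defaults follow common practice for mixed-integer GA solvers: binary
#' tournament selection, scattered crossover with fraction 0.8, mutation
#' rate 0.2 with a mutation step that adapts (shrinks) over generations,
#' elitism of 2.
#'
#' @param population_size,generations,elitism GA size controls.
#' @param crossover_fraction,mutation_rate operator rates.
#' @param seed integer seed.
#' @param polish run a bound-constrained quasi-Newton refinement of the
#'   continuous genes from the best feasible individual (default TRUE).
#' @return object of class `inversion_ga_config`.
#' @export
inversion_ga_config <- function(population_size = 100, generations = 200,
                                elitism = 2, crossover_fraction = 0.8,
                                mutation_rate = 0.2, seed = 1,
                                polish = TRUE) {
  structure(list(population_size = population_size,
                 generations = generations, elitism = elitism,
                 crossover_fraction = crossover_fraction,
                 mutation_rate = mutation_rate, seed = seed,
                 polish = polish),
            class = "inversion_ga_config")
}

#' Inversion objective
#'
#' Squared deviation of the model-predicted properties from the reference:
#' `(logkw_hat - logkw_ref)^2 + (logKi_hat - logKi_ref)^2`.
#'
#' @param x raw-unit descriptor vector (or matrix of rows).
#' @param problem an `inversion_problem`.
#' @param check validate bounds and kinds (default TRUE).
#' @return numeric objective value(s).
#' @export
inversion_objective <- function(x, problem, check = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (check) {
    for (i in seq_len(nrow(x))) check_kinds(x[i, ], problem)
  }
  pr <- predict(problem$model, x)$predictions
  unname((pr[, 1] - problem$reference$logkw_ref)^2 +
           (pr[, 2] - problem$reference$logKi_ref)^2)
}

check_kinds <- function(x, problem) {
  lo <- problem$bounds$lower; hi <- problem$bounds$upper
  if (any(x < lo - 1e-9) || any(x > hi + 1e-9))
    stop("descriptor vector violates the training bounds")
  bad <- problem$kinds == "binary" & !(x %in% c(0, 1))
  if (any(bad)) stop("binary descriptor takes a value outside {0,1}")
  bad <- problem$kinds == "integer" & x != round(x)
  if (any(bad)) stop("integer descriptor takes a non-whole value")
  invisible(TRUE)
}

# constraint values for a population matrix of raw-unit rows
constraint_values <- function(X, problem) {
  m <- problem$model
  Xs <- apply_scaling(X, m$x_scaling)
  Tn <- Xs %*% m$Rstar
  t2 <- rowSums((Tn %*% solve(m$score_cov)) * Tn)
  res <- Xs - tcrossprod(Tn, m$P)
  rn <- rowSums(res^2)
  if (!problem$squared_residual) rn <- sqrt(rn)
  list(t2 = t2, resid = rn)
}

#' Invert the PLS model
#'
#' Solves the constrained mixed-integer program of
#' [build_inversion_problem()] with a genetic algorithm: continuous genes
#' move within the training box, binary/integer genes on their lattices,
#' and individuals are ranked feasibility-first (any feasible individual
#' dominates any infeasible one; infeasible individuals are ordered by
#' total constraint violation).  The initial population is seeded with the
#' training compounds -- every in-domain training compound is feasible by
#' construction -- plus random box samples.  When no feasible individual is
#' found the best-violation solution is returned flagged infeasible.
#'
#' @param problem an `inversion_problem`.
#' @return object of class `inversion_solution` with `x_star` (raw),
#'   `x_star_scaled`, `predicted` (named logkw/logKi), `objective`,
#'   `t2_value`, `recon_residual`, `feasible`, and the constraint limits.
#' @export
invert_model <- function(problem) {
  ga <- problem$ga
  m <- problem$model
  p <- m$p
  lo <- problem$bounds$lower; hi <- problem$bounds$upper
  kinds <- problem$kinds
  cont <- kinds == "continuous"
  intg <- kinds == "integer"
  binr <- kinds == "binary"
  npop <- ga$population_size

  rand_row <- function() {
    x <- lo + stats::runif(p) * (hi - lo)
    x[intg] <- round(x[intg])
    x[binr] <- stats::rbinom(sum(binr), 1, 0.5) * (hi[binr] - lo[binr]) +
      lo[binr]
    x[binr] <- pmin(pmax(round(x[binr]), lo[binr]), hi[binr])
    x
  }
  clamp <- function(x) {
    x <- pmin(pmax(x, lo), hi)
    x[intg] <- pmin(pmax(round(x[intg]), lo[intg]), hi[intg])
    x[binr] <- pmin(pmax(round(x[binr]), lo[binr]), hi[binr])
    x
  }
  evaluate <- function(P) {
    cons <- constraint_values(P, problem)
    viol <- pmax(cons$t2 - problem$c1, 0) +
      pmax(cons$resid - problem$c2, 0)
    obj <- inversion_objective(P, problem, check = FALSE)
    list(obj = obj, viol = viol, t2 = cons$t2, resid = cons$resid,
         # feasibility-first scalar rank key
         key = ifelse(viol <= 0, obj, max(obj[viol <= 0], 0, na.rm = TRUE) +
                        1 + viol))
    }

  local_seed(ga$seed, {
    ntrain <- min(nrow(problem$train_X), npop %/% 2)
    P <- rbind(problem$train_X[seq_len(ntrain), , drop = FALSE],
               t(vapply(seq_len(npop - ntrain), function(i) rand_row(),
                        numeric(p))))
    ev <- evaluate(P)
    for (gen in seq_len(ga$generations)) {
      ord <- order(ev$key)
      elite <- P[ord[seq_len(ga$elitism)], , drop = FALSE]
      # binary tournament on the feasibility-first key
      pick <- function() {
        c2_ <- sample.int(npop, 2)
        c2_[which.min(ev$key[c2_])]
      }
      # adaptive mutation scale shrinks as the search converges
      step <- 0.3 * (1 - gen / (ga$generations + 1))
      children <- matrix(0, npop, p)
      for (i in seq_len(npop)) {
        if (i <= ga$elitism) { children[i, ] <- elite[i, ]; next }
        a <- P[pick(), ]; b <- P[pick(), ]
        child <- if (stats::runif(1) < ga$crossover_fraction) {
          mask <- stats::runif(p) < 0.5   # scattered crossover
          ifelse(mask, a, b)
        } else a
        mut <- stats::runif(p) < ga$mutation_rate
        if (any(mut & cont))
          child[mut & cont] <- child[mut & cont] +
            stats::rnorm(sum(mut & cont)) * step *
            (hi[mut & cont] - lo[mut & cont])
        if (any(mut & intg))
          child[mut & intg] <- child[mut & intg] +
            sample(c(-1, 1), sum(mut & intg), replace = TRUE)
        if (any(mut & binr))
          child[mut & binr] <- lo[mut & binr] + hi[mut & binr] -
            child[mut & binr]   # flip within its two-point lattice
        children[i, ] <- clamp(child)
      }
      P <- children
      ev <- evaluate(P)
    }
    best <- which.min(ev$key)
    x_best <- P[best, ]

    if (ga$polish && any(cont) && ev$viol[best] <= 0) {
      # quasi-Newton refinement of the continuous genes; discrete genes
      # frozen; constraints as smooth quadratic penalties, feasibility
      # re-checked afterwards
      fixed <- x_best
      pen <- function(z) {
        x <- fixed; x[cont] <- z
        cons <- constraint_values(matrix(x, 1), problem)
        inversion_objective(x, problem, check = FALSE) +
          1e4 * (pmax(cons$t2 - problem$c1, 0)^2 +
                   pmax(cons$resid - problem$c2, 0)^2)
      }
      opt <- tryCatch(
        stats::optim(x_best[cont], pen, method = "L-BFGS-B",
                     lower = lo[cont], upper = hi[cont]),
        error = function(e) NULL)
      if (!is.null(opt)) {
        cand <- fixed; cand[cont] <- opt$par
        cev <- evaluate(matrix(cand, 1))
        if (cev$viol <= 0 && cev$obj < ev$obj[best]) {
          x_best <- cand
          ev$obj[best] <- cev$obj; ev$viol[best] <- cev$viol
          ev$t2[best] <- cev$t2; ev$resid[best] <- cev$resid
        }
      }
    }

    # model-consistent solution: the objective is flat in residual
    # directions (off the loading plane), so project the continuous
    # coordinates onto the plane -- scores, predictions and T2 are
    # unchanged, the reconstruction residual drops to its minimum
    if (any(cont)) {
      xs <- apply_scaling(matrix(x_best, 1), m$x_scaling)
      tn <- xs %*% m$Rstar
      xs_plane <- tcrossprod(tn, m$P)
      cand <- x_best
      cand[cont] <- drop(invert_scaling(xs_plane, m$x_scaling))[cont]
      cand <- clamp(cand)
      cev <- evaluate(matrix(cand, 1))
      if (cev$viol <= 0 && cev$obj <= ev$obj[best] + 1e-9) {
        x_best <- cand
        ev$obj[best] <- cev$obj; ev$viol[best] <- cev$viol
        ev$t2[best] <- cev$t2; ev$resid[best] <- cev$resid
      }
    }

    pr <- predict(m, x_best)$predictions
    structure(list(
      x_star = stats::setNames(x_best, m$descriptor_names),
      x_star_scaled = drop(apply_scaling(x_best, m$x_scaling)),
      predicted = c(logkw = unname(pr[1, 1]), logKi = unname(pr[1, 2])),
      objective = unname(ev$obj[best]),
      t2_value = unname(ev$t2[best]),
      recon_residual = unname(ev$resid[best]),
      feasible = unname(ev$viol[best] <= 0),
      c1 = problem$c1, c2 = problem$c2),
      class = "inversion_solution")
  })
}

#' @export
print.inversion_solution <- function(x, ...) {
  cat("inversion_solution:", if (x$feasible) "feasible" else "INFEASIBLE",
      "\n  objective =", signif(x$objective, 5),
      "\n  predicted logkw =", signif(x$predicted["logkw"], 5),
      ", logKi =", signif(x$predicted["logKi"], 5),
      "\n  T2 =", signif(x$t2_value, 5), "(limit", signif(x$c1, 5), ")",
      "\n  residual =", signif(x$recon_residual, 5),
      "(limit", signif(x$c2, 5), ")\n")
  invisible(x)
}

#' Write an inversion solution (CSV + JSON summary)
#' @param solution an `inversion_solution`.
#' @param csv_path per-descriptor CSV (descriptor, raw, scaled).
#' @param json_path summary JSON path (objective, T2, residual, feasibility).
#' @return `csv_path`, invisibly.
#' @export
write_inversion_solution <- function(solution, csv_path, json_path = NULL) {
  utils::write.csv(data.frame(descriptor = names(solution$x_star),
                              raw = unname(solution$x_star),
                              scaled = unname(solution$x_star_scaled)),
                   csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(objective = solution$objective,
                              predicted = as.list(solution$predicted),
                              t2 = solution$t2_value,
                              recon_residual = solution$recon_residual,
                              feasible = solution$feasible,
                              c1 = solution$c1, c2 = solution$c2),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
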