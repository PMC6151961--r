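#' Euclidean distances of library compounds to the inversion solution
#'
#' Distances are computed in raw descriptor units on the model's selected
#' descriptors (set `scaling` to compute them in autoscaled space instead).
#'
#' @param x_star named raw-unit descriptor vector (e.g.
#'   `inversion_solution$x_star`).
#' @param library a `descriptor_table` (or matrix) restricted to, or
#'   containing, the same descriptors.
#' @param scaling optional list(center, scale): when supplied both sides
#'   are scaled before the distance.
#' @return named numeric vector of distances, one per library compound.
#' @export
euclidean_distances <- function(x_star, library, scaling = NULL) {
  L <- if (inherits(library, "descriptor_table")) library$values
       else as.matrix(library)
  if (!is.null(names(x_star)) && !is.null(colnames(L))) {
    missing_d <- setdiff(names(x_star), colnames(L))
    if (length(missing_d))
      stop("library lacks descriptors: ", paste(missing_d, collapse = ", "))
    L <- L[, names(x_star), drop = FALSE]
  } else if (ncol(L) != length(x_star)) {
    stop("descriptor count mismatch between x_star and library")
  }
  if (!is.null(scaling)) {
    L <- apply_scaling(L, scaling)
    x_star <- drop(apply_scaling(x_star, scaling))
  }
  d <- sqrt(rowSums(sweep(L, 2, x_star)^2))
  stats::setNames(d, rownames(L))
}

#' Leverage admissibility of library compounds
#'
#' Keeps compounds whose leverage relative to the model training set does
#' not exceed the warning threshold `h*` -- the structural-similarity
#' pre-screen applied before distance ranking.
#'
#' @param library `descriptor_table` or matrix on the model descriptors.
#' @param X_train raw-unit training matrix.
#' @param h_star threshold; default [leverage_threshold()] of the training
#'   dimensions.
#' @return logical vector, TRUE = admissible.
#' @export
admissibility_filter <- function(library, X_train,
                                 h_star = leverage_threshold(
                                   ncol(as.matrix(X_train)),
                                   nrow(as.matrix(X_train)))) {
  L <- if (inherits(library, "descriptor_table")) library$values
       else as.matrix(library)
  h <- leverage(X_train, L)
  stats::setNames(h <= h_star, rownames(L))
}

#' Composite induced-fit docking score
#'
#' `IFDScore = 1.0 * GlideScore + 0.05 * PrimeEnergy` (kcal/mol); more
#' negative is better.
#'
#' @param glide_score,prime_energy numeric vectors (kcal/mol).
#' @return numeric vector of composite scores.
#' @export
ifd_score <- function(glide_score, prime_energy) {
  if (any(!is.finite(glide_score)) || any(!is.finite(prime_energy)))
    stop("docking score components must be finite")
  1.0 * glide_score + 0.05 * prime_energy
}

#' Fuse inverse-QSPR and docking ranks
#'
#' Final rank = arithmetic mean of the two ranks, rounded half up (3.5
#' becomes 4).  Equal means give equal final ranks.  Ligands missing either
#' rank are dropped with a warning.
#'
#' @param iqspr_ranks,docking_ranks named integer vectors over the same
#'   ligand set.
#' @return named integer vector of fused ranks.
#' @export
final_ranking <- function(iqspr_ranks, docking_ranks) {
  if (is.null(names(iqspr_ranks)) || is.null(names(docking_ranks))) {
    if (length(iqspr_ranks) != length(docking_ranks))
      stop("unnamed rank vectors must have equal length")
    names(iqspr_ranks) <- names(docking_ranks) <-
      paste0("lig", seq_along(iqspr_ranks))
  }
  common <- intersect(names(iqspr_ranks), names(docking_ranks))
  dropped <- setdiff(union(names(iqspr_ranks), names(docking_ranks)), common)
  if (length(dropped))
    warning("ligands missing one rank excluded: ",
            paste(dropped, collapse = ", "))
  m <- (iqspr_ranks[common] + docking_ranks[common]) / 2
  stats::setNames(as.integer(floor(m + 0.5)), common)
}

#' Screen a candidate library against an inversion solution
#'
#' Full first-stage ranking: leverage admissibility against the model
#' training set, Euclidean distance to `x_star` over admissible ligands,
#' and a dense inverse-QSPR rank (1 = closest; distance ties broken by
#' ligand id).  When docking input is supplied the composite IFD score is
#' computed, ligands are ranked by it (most negative first), and the fused
#' final rank is added.
#'
#' @param x_star named raw-unit descriptor vector.
#' @param library `descriptor_table` of candidate ligands.
#' @param X_train raw-unit training matrix on the same descriptors (used
#'   for the leverage filter); NULL skips admissibility.
#' @param docking optional data.frame with `compound_id` plus either
#'   `ifd_score` or `glide_score` and `prime_energy`.
#' @param h_star leverage threshold override.
#' @param scaling optional scaling for the distances (see
#'   [euclidean_distances()]).
#' @return object of class `screening_ranking`: data.frame with columns
#'   `compound_id`, `dist_x`, `leverage_ok`, `iqspr_rank`, and (with
#'   docking) `docking_score`, `docking_rank`, `final_rank`; ordered by
#'   `iqspr_rank`, inadmissible ligands last with NA ranks.
#' @export
screen_library <- function(x_star, library, X_train = NULL, docking = NULL,
                           h_star = NULL, scaling = NULL) {
  d <- euclidean_distances(x_star, library, scaling = scaling)
  ids <- if (inherits(library, "descriptor_table")) library$compound_ids
         else rownames(library) %||% paste0("lig", seq_along(d))
  ok <- rep(TRUE, length(d))
  if (!is.null(X_train)) {
    Lm <- if (inherits(library, "descriptor_table"))
      library$values[, names(x_star), drop = FALSE]
    else as.matrix(library)[, names(x_star), drop = FALSE]
    Xt <- as.matrix(X_train)[, names(x_star), drop = FALSE]
    if (is.null(h_star)) h_star <- leverage_threshold(ncol(Xt), nrow(Xt))
    ok <- unname(admissibility_filter(Lm, Xt, h_star))
  }
  out <- data.frame(compound_id = ids, dist_x = unname(d),
                    leverage_ok = ok, iqspr_rank = NA_integer_,
                    stringsAsFactors = FALSE)
  adm <- which(ok)
  ord <- adm[order(out$dist_x[adm], out$compound_id[adm])]
  out$iqspr_rank[ord] <- seq_along(ord)
  if (!is.null(docking)) {
    if (!"ifd_score" %in% names(docking)) {
      if (!all(c("glide_score", "prime_energy") %in% names(docking)))
        stop("docking input needs 'ifd_score' or glide_score/prime_energy")
      docking$ifd_score <- ifd_score(docking$glide_score,
                                     docking$prime_energy)
    }
    out$docking_score <- docking$ifd_score[match(out$compound_id,
                                                 docking$compound_id)]
    out$docking_rank <- NA_integer_
    have <- which(!is.na(out$docking_score) & out$leverage_ok)
    dord <- have[order(out$docking_score[have], out$compound_id[have])]
    out$docking_rank[dord] <- seq_along(dord)
    both <- !is.na(out$iqspr_rank) & !is.na(out$docking_rank)
    out$final_rank <- NA_integer_
    out$final_rank[both] <- unname(final_ranking(
      stats::setNames(out$iqspr_rank[both], out$compound_id[both]),
      stats::setNames(out$docking_rank[both], out$compound_id[both])))
  }
  out <- out[order(!out$leverage_ok, out$iqspr_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_ranking", "data.frame")
  out
}
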