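#' Construct a descriptor table
#'
#' The central X-space container: a numeric compounds-by-descriptors matrix
#' with per-descriptor kind metadata.  Molecular descriptors come in three
#' kinds -- continuous (real-valued, e.g. WHIM or Burden-matrix eigenvalues),
#' integer counts, and binary presence/absence fingerprints -- and several
#' downstream rules (the zero filter, mixed-integer inversion) depend on the
#' kind.
#'
#' @param values numeric matrix, compounds in rows, descriptors in columns.
#' @param compound_ids character vector of unique compound identifiers; taken
#'   from `rownames(values)` when missing.
#' @param descriptor_names character vector of unique descriptor names; taken
#'   from `colnames(values)` when missing.
#' @param kinds per-descriptor kind, each one of `"continuous"`, `"integer"`,
#'   `"binary"`; inferred from the data via [infer_kinds()] when `NULL`.
#' @return an object of class `descriptor_table` with elements `values`
#'   (matrix with dimnames), `compound_ids`, `descriptor_names`, `kinds`.
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             descriptor_names = colnames(values),
                             kinds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_ids))
    compound_ids <- paste0("cmp", seq_len(nrow(values)))
  if (is.null(descriptor_names))
    descriptor_names <- paste0("desc", seq_len(ncol(values)))
  compound_ids <- as.character(compound_ids)
  descriptor_names <- as.character(descriptor_names)
  if (length(compound_ids) != nrow(values))
    stop("compound_ids length (", length(compound_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (length(descriptor_names) != ncol(values))
    stop("descriptor_names length (", length(descriptor_names),
         ") does not match number of columns (", ncol(values), ")")
  dup <- unique(compound_ids[duplicated(compound_ids)])
  if (length(dup))
    stop("duplicated compound ids: ", paste(dup, collapse = ", "))
  dup <- unique(descriptor_names[duplicated(descriptor_names)])
  if (length(dup))
    stop("duplicated descriptor names: ", paste(dup, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("descriptor table contains missing or non-finite values")
  if (is.null(kinds)) {
    kinds <- infer_kinds(values)
  } else {
    kinds <- match.arg(kinds, c("continuous", "integer", "binary"),
                       several.ok = TRUE)
    if (length(kinds) == 1L) kinds <- rep(kinds, ncol(values))
    if (length(kinds) != ncol(values))
      stop("kinds length does not match number of descriptors")
    for (j in seq_len(ncol(values))) {
      v <- values[, j]
      if (kinds[j] == "binary" && !all(v %in% c(0, 1)))
        stop("descriptor '", descriptor_names[j],
             "' declared binary but contains values outside {0,1}")
      if (kinds[j] == "integer" && any(v != round(v)))
        stop("descriptor '", descriptor_names[j],
             "' declared integer but contains non-whole values")
    }
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  names(kinds) <- descriptor_names
  structure(list(values = values, compound_ids = compound_ids,
                 descriptor_names = descriptor_names, kinds = kinds),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table: ", length(x$compound_ids), " compounds x ",
      length(x$descriptor_names), " descriptors (",
      sum(x$kinds == "continuous"), " continuous, ",
      sum(x$kinds == "integer"), " integer, ",
      sum(x$kinds == "binary"), " binary)\n", sep = "")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Infer descriptor kinds from values
#'
#' Deterministic inference: a column whose values all lie in `{0, 1}` is
#' binary; a column of whole numbers is integer; anything else is continuous.
#' The rule is idempotent and independent of row order.
#'
#' @param values numeric matrix.
#' @return character vector of kinds, one per column.
#' @export
infer_kinds <- function(values) {
  values <- as.matrix(values)
  vapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    if (all(v %in% c(0, 1))) "binary"
    else if (all(v == round(v))) "integer"
    else "continuous"
  }, character(1))
}

#' Read a descriptor table from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header row of descriptor
#' names and the compound identifier in the first column.  Kinds are read
#' from an optional two-column CSV (`descriptor,kind`) or inferred.
#'
#' @param path CSV file path.
#' @param kinds_path optional CSV mapping descriptor name to kind.
#' @return a [descriptor_table()].
#' @export
read_descriptor_table <- function(path, kinds_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("descriptor CSV must have an id column plus data")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    first <- names(df[-1])[bad[1]]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad[1] + 1]]))))[1]
    stop("non-numeric value in column '", first, "' (row ",
         if (is.na(badrow)) "?" else badrow, ")")
  }
  kinds <- NULL
  if (!is.null(kinds_path)) {
    kdf <- utils::read.csv(kinds_path, stringsAsFactors = FALSE)
    kmap <- stats::setNames(kdf[[2]], kdf[[1]])
    missing_k <- setdiff(colnames(m), names(kmap))
    kinds <- ifelse(colnames(m) %in% names(kmap),
                    kmap[colnames(m)], NA_character_)
    if (anyNA(kinds)) {
      inferred <- infer_kinds(m)
      kinds[is.na(kinds)] <- inferred[is.na(kinds)]
    }
    if (length(missing_k) == ncol(m)) kinds <- as.character(kinds)
  }
  descriptor_table(m, compound_ids = ids, kinds = kinds)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; values are written with full
#' precision (17 significant digits) so the round trip is bit-exact.
#'
#' @param desc a `descriptor_table`.
#' @param path output CSV path.
#' @param kinds_path optional path for the descriptor-kind CSV.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(desc, path, kinds_path = NULL) {
  df <- data.frame(compound_id = desc$compound_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- desc$values
  for (j in seq_len(ncol(vals)))
    df[[desc$descriptor_names[j]]] <- formatC(vals[, j], digits = 17,
                                              format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(kinds_path))
    utils::write.csv(data.frame(descriptor = desc$descriptor_names,
                                kind = unname(desc$kinds)),
                     kinds_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a property table
#'
#' Y-space container holding the two modelled drug properties:
#' chromatographic lipophilicity `logkw` (dimensionless, the extrapolated
#' retention factor at 0% organic modifier) and `logKi` (log10 of the
#' inhibition constant in nM).
#'
#' @param compound_ids character vector of compound identifiers.
#' @param logkw,logKi numeric vectors aligned with `compound_ids`.
#' @return an object of class `property_table`.
#' @export
property_table <- function(compound_ids, logkw, logKi) {
  compound_ids <- as.character(compound_ids)
  if (anyDuplicated(compound_ids))
    stop("duplicated compound ids in property table")
  if (length(logkw) != length(compound_ids) ||
      length(logKi) != length(compound_ids))
    stop("property columns must match compound_ids in length")
  if (any(!is.finite(logkw)) || any(!is.finite(logKi)))
    stop("property table contains non-finite values")
  structure(list(compound_ids = compound_ids,
                 logkw = as.numeric(logkw), logKi = as.numeric(logKi)),
            class = "property_table")
}

#' Read a property table from CSV
#'
#' @param path CSV with columns `compound_id`, `logkw`, `logKi` (first column
#'   is taken as the id regardless of its header).
#' @return a [property_table()].
#' @export
read_property_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- tolower(names(df))
  kw <- which(cols == "logkw")[1]
  ki <- which(cols == "logki")[1]
  if (is.na(kw) || is.na(ki))
    stop("property CSV must contain 'logkw' and 'logKi' columns")
  property_table(df[[1]], df[[kw]], df[[ki]])
}

#' Write a property table to CSV
#' @param props a `property_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(props, path) {
  df <- data.frame(compound_id = props$compound_ids,
                   logkw = formatC(props$logkw, digits = 17, format = "g"),
                   logKi = formatC(props$logKi, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Property matrix of a property table
#' @param props a `property_table`.
#' @return n x 2 matrix with columns `logkw`, `logKi`.
#' @export
property_matrix <- function(props) {
  cbind(logkw = props$logkw, logKi = props$logKi)
}

#' Reference drug properties for model inversion
#'
#' The target the inverted model is steered toward, e.g. the properties of a
#' known potent, lipophilic inhibitor.
#'
#' @param logkw_ref,logKi_ref finite reals.
#' @return object of class `reference_properties`.
#' @export
reference_properties <- function(logkw_ref, logKi_ref) {
  if (!is.finite(logkw_ref) || !is.finite(logKi_ref))
    stop("reference properties must be finite")
  structure(list(logkw_ref = as.numeric(logkw_ref),
                 logKi_ref = as.numeric(logKi_ref)),
            class = "reference_properties")
}

#' Isocratic retention series
#'
#' Pairs of organic-modifier volume fraction phi and measured log retention
#' factor, the raw input to the linear lipophilicity extrapolation.
#'
#' @param phi numeric vector in `[0, 1]`, distinct values.
#' @param logk numeric vector, same length.
#' @return object of class `retention_series`.
#' @export
retention_series <- function(phi, logk) {
  if (length(phi) != length(logk)) stop("phi and logk lengths differ")
  if (length(phi) < 2) stop("need at least 2 retention points")
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  if (anyDuplicated(phi)) stop("phi values must be distinct")
  structure(list(phi = as.numeric(phi), logk = as.numeric(logk)),
            class = "retention_series")
}

#' Align a descriptor table with a property table
#'
#' Reorders the descriptor rows to the property-table compound order (the
#' canonical order for all downstream splitting and modelling).
#'
#' @param desc a `descriptor_table`.
#' @param props a `property_table`; every id must be present in `desc`.
#' @return list with the reordered `desc`, `props`, and the matrices `X`
#'   (descriptors) and `Y` (two-column property matrix).
#' @export
align_tables <- function(desc, props) {
  missing_ids <- setdiff(props$compound_ids, desc$compound_ids)
  if (length(missing_ids))
    stop("compound ids missing from descriptor table: ",
         paste(missing_ids, collapse = ", "))
  idx <- match(props$compound_ids, desc$compound_ids)
  desc2 <- descriptor_table(desc$values[idx, , drop = FALSE],
                            compound_ids = props$compound_ids,
                            descriptor_names = desc$descriptor_names,
                            kinds = unname(desc$kinds))
  list(desc = desc2, props = props,
       X = desc2$values, Y = property_matrix(props))
}

#' Subset a descriptor table by descriptor names or compound ids
#' @param desc a `descriptor_table`.
#' @param descriptors optional character vector of descriptor names to keep.
#' @param compounds optional character vector of compound ids to keep.
#' @return the subset `descriptor_table` (order follows the arguments).
#' @export
subset_descriptors <- function(desc, descriptors = NULL, compounds = NULL) {
  if (is.null(descriptors)) descriptors <- desc$descriptor_names
  if (is.null(compounds)) compounds <- desc$compound_ids
  bad <- setdiff(descriptors, desc$descriptor_names)
  if (length(bad)) stop("unknown descriptors: ", paste(bad, collapse = ", "))
  bad <- setdiff(compounds, desc$compound_ids)
  if (length(bad)) stop("unknown compounds: ", paste(bad, collapse = ", "))
  descriptor_table(desc$values[compounds, descriptors, drop = FALSE],
                   compound_ids = compounds,
                   descriptor_names = descriptors,
                   kinds = unname(desc$kinds[descriptors]))
}
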