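#' Pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()].  Either
#' `descriptor_csv`/`property_csv` point at input files, or a
#' `synthetic_spec` generates the inputs in memory.
#'
#' @param descriptor_csv,property_csv,kinds_csv,docking_csv input paths
#'   (docking optional).
#' @param library_csv optional candidate-library CSV; the training
#'   descriptor table doubles as the library when absent.
#' @param synthetic optional [synthetic_spec()] replacing the CSV inputs.
#' @param rsd_pct,corr_threshold pre-selection filter settings.
#' @param n_train Kennard-Stone training-set size.
#' @param ga a [ga_config()] for descriptor selection.
#' @param reference a [reference_properties()]; defaults to the properties
#'   of the training compound whose prediction is closest to the property
#'   medians (a purely synthetic stand-in reference).
#' @param alpha significance level for the applicability-domain limits.
#' @param inversion_ga an [inversion_ga_config()].
#' @param seed master seed recorded in the run metadata.
#' @return object of class `run_config`.
#' @export
run_config <- function(descriptor_csv = NULL, property_csv = NULL,
                       kinds_csv = NULL, docking_csv = NULL,
                       library_csv = NULL, synthetic = NULL,
                       rsd_pct = 5, corr_threshold = 0.8, n_train = 33,
                       ga = ga_config(), reference = NULL, alpha = 0.05,
                       inversion_ga = inversion_ga_config(), seed = 1) {
  if (is.null(synthetic) &&
      (is.null(descriptor_csv) || is.null(property_csv)))
    stop("supply descriptor_csv + property_csv, or a synthetic spec")
  structure(list(descriptor_csv = descriptor_csv,
                 property_csv = property_csv, kinds_csv = kinds_csv,
                 docking_csv = docking_csv, library_csv = library_csv,
                 synthetic = synthetic, rsd_pct = rsd_pct,
                 corr_threshold = corr_threshold, n_train = n_train,
                 ga = ga, reference = reference, alpha = alpha,
                 inversion_ga = inversion_ga, seed = seed),
            class = "run_config")
}

#' Run the full screening pipeline
#'
#' Executes filter -> split -> GA selection -> PLS fit -> diagnostics ->
#' inversion -> library screening -> (optional) rank fusion, writing every
#' stage artifact into `out_dir`: `filter_report.csv`, `split.json`,
#' `selection.csv` + `ga_history.csv`, `model.json`, `diagnostics.csv`,
#' `solution.csv` + `solution.json`, `ranking.csv`, and `run_log.json`
#' (seeds, parameters, stage status, config hash).  A stage failure aborts
#' with the stage name; artifacts of completed stages are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return list with the principal in-memory results (`filter_report`,
#'   `split`, `selection`, `model`, `diagnostics`, `solution`, `ranking`),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(digest_config(config), 1, 12)
  log <- list(seed = config$seed, config_hash = cfg_hash,
              package_version = as.character(
                utils::packageVersion("plsinvert")),
              stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      log$stages[[name]] <<- paste("FAILED:", conditionMessage(e))
      jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log$stages[[name]] <<- "ok"
    res
  }

  inputs <- stage("load", {
    if (!is.null(config$synthetic)) {
      ds <- generate_synthetic(config$synthetic)
      list(desc = ds$desc, props = ds$props, truth = ds$truth)
    } else {
      list(desc = read_descriptor_table(config$descriptor_csv,
                                        config$kinds_csv),
           props = read_property_table(config$property_csv),
           truth = NULL)
    }
  })
  aligned <- stage("align", align_tables(inputs$desc, inputs$props))

  report <- stage("filter", {
    r <- filter_descriptors(aligned$desc, aligned$props,
                            rsd_pct = config$rsd_pct,
                            corr_threshold = config$corr_threshold)
    write_filter_report(r, file.path(out_dir, "filter_report.csv"))
    r
  })

  split <- stage("split", {
    s <- kennard_stone_split(report$desc, config$n_train)
    jsonlite::write_json(list(train_ids = s$train_ids,
                              test_ids = s$test_ids),
                         file.path(out_dir, "split.json"),
                         auto_unbox = FALSE)
    s
  })

  Xall <- report$desc$values
  Yall <- property_matrix(aligned$props)
  rownames(Yall) <- aligned$props$compound_ids
  Xtr <- Xall[split$train_ids, , drop = FALSE]
  Xte <- Xall[split$test_ids, , drop = FALSE]
  Ytr <- Yall[split$train_ids, , drop = FALSE]
  Yte <- Yall[split$test_ids, , drop = FALSE]

  selection <- stage("select", {
    sel <- run_ga(Xtr, Ytr, Xte, Yte, config$ga)
    utils::write.csv(data.frame(descriptor = sel$selected_names),
                     file.path(out_dir, "selection.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(generation = seq_along(sel$history),
                                best_eta = sel$history),
                     file.path(out_dir, "ga_history.csv"),
                     row.names = FALSE, quote = FALSE)
    sel
  })

  Xtr_s <- Xtr[, selection$selected_names, drop = FALSE]
  Xte_s <- Xte[, selection$selected_names, drop = FALSE]

  model <- stage("fit", {
    # keep A below the subset size so the X-residual diagnostics (DModX)
    # and the inversion residual constraint are defined
    A_fit <- max(1L, min(selection$A_chosen, ncol(Xtr_s) - 1L))
    m <- fit_pls(Xtr_s, Ytr, A = A_fit)
    write_pls_model(m, file.path(out_dir, "model.json"))
    m
  })

  diagnostics <- stage("diagnose", {
    d <- diagnose(model, Xtr_s, Ytr,
                  X_query = rbind(Xtr_s, Xte_s),
                  Y_query = rbind(Ytr, Yte), alpha = config$alpha)
    utils::write.csv(as.data.frame(d),
                     file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE, quote = FALSE)
    d
  })

  solution <- stage("invert", {
    ref <- config$reference
    if (is.null(ref)) {
      med <- apply(Ytr, 2, stats::median)
      ref <- reference_properties(med[1], med[2])
    }
    kinds <- unname(report$desc$kinds[selection$selected_names])
    prob <- build_inversion_problem(model, ref, Xtr_s, kinds = kinds,
                                    alpha = config$alpha,
                                    ga = config$inversion_ga)
    sol <- invert_model(prob)
    write_inversion_solution(sol, file.path(out_dir, "solution.csv"),
                             file.path(out_dir, "solution.json"))
    sol
  })

  ranking <- stage("screen", {
    lib <- if (!is.null(config$library_csv))
      read_descriptor_table(config$library_csv)
    else subset_descriptors(report$desc,
                            descriptors = selection$selected_names)
    docking <- NULL
    if (!is.null(config$docking_csv)) {
      docking <- utils::read.csv(config$docking_csv,
                                 stringsAsFactors = FALSE)
    } else {
      warning("no docking input; ranking stops at the inverse-QSPR rank")
    }
    r <- screen_library(solution$x_star, lib, X_train = Xtr_s,
                        docking = docking)
    utils::write.csv(as.data.frame(r), file.path(out_dir, "ranking.csv"),
                     row.names = FALSE, quote = FALSE)
    r
  })
  log$stages[["rank"]] <- if (is.null(config$docking_csv))
    "skipped: no docking input" else "ok"

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(filter_report = report, split = split,
                 selection = selection, model = model,
                 diagnostics = diagnostics, solution = solution,
                 ranking = ranking, log = log))
}

# order-stable hash of the config (no external digest dependency)
digest_config <- function(config) {
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # simple 31-base polynomial hash, hex encoded
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
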