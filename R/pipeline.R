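# Config-driven pipeline runner: ties the simulators, fitters and
# forecasting together into reproducible runs that write CSV/JSON artifacts.
# A thin command-line wrapper over this function ships in
# inst/scripts/emels_cli.R.

#' Run a configured pipeline
#'
#' Executes one named pipeline step and writes its artifacts to
#' `config$out_dir`.  `config` is a named list (or the path of a YAML file
#' holding one) with at least `command` and `out_dir`; every stochastic
#' command honours `config$seed` and records it in its outputs.
#'
#' Commands:
#' \describe{
#'   \item{simulate}{`scenario = "tree"` (default) or `"linear"`; writes the
#'     long CSV plus a `truths` JSON sidecar (parameters, per-person random
#'     effects).}
#'   \item{fit}{`model = "emels"` or `"mem_ar1"`; reads `data` (CSV) with
#'     the column roles in `columns` (keys outcome, id, time, predictors),
#'     writes a parameter CSV and a fit summary JSON.}
#'   \item{tree}{alternating tree fit; writes an indented tree text
#'     artifact and a summary JSON.}
#'   \item{lasso}{penalty path; writes the path table CSV and the selected
#'     model summary.}
#'   \item{benchmark}{fits the requested `models` on a train/test split and
#'     writes the per-model-per-task forecast accuracy table.}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @return invisibly, a list with the computed objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$command))
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  cmd <- config$command
  art <- list()

  write_json <- function(x, file) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("writing JSON artifacts requires the jsonlite package")
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    file.path(out_dir, file)
  }

  read_config_data <- function() {
    cols <- config$columns
    read_long_csv(config$data, outcome = cols$outcome, id = cols$id,
                  time = cols$time,
                  predictors = as.character(cols$predictors %||% character()))
  }

  if (cmd == "simulate") {
    scen <- config$scenario %||% "tree"
    ld <- if (scen == "tree") {
      simulate_tree_data(I = config$I %||% 200, T_len = config$T %||% 51,
                         seed = seed)
    } else {
      simulate_emels_data(I = config$I %||% 200, T_len = config$T %||% 51,
                          beta = config$beta %||% c(10, 0.3),
                          s0 = config$s0 %||% -0.67,
                          r0 = config$r0 %||% 0.26,
                          Phi = diag(config$phi_diag %||% c(1, 0.5, 0.5)),
                          seed = seed)
    }
    art$data <- file.path(out_dir, "simulated.csv")
    write_long_csv(ld, art$data)
    tr <- attr(ld, "truth")
    tr$v <- NULL
    tr$Phi <- as.vector(tr$Phi)
    tr$seed <- seed
    art$truths <- write_json(tr, "truths.json")
    return(invisible(list(data = ld, artifacts = art)))
  }

  if (cmd %in% c("fit", "tree", "lasso")) {
    ld <- read_config_data()
    fml <- if (!is.null(config$formula)) stats::as.formula(config$formula)
           else NULL
    Q <- config$Q %||% 10L
    if (cmd == "fit") {
      fit <- if ((config$model %||% "emels") == "emels")
        emels(fml, ld, Q = Q, se = isTRUE(config$se))
        else mem_ar1(fml, ld, se = isTRUE(config$se))
      utils::write.csv(fit$report, file.path(out_dir, "parameters.csv"),
                       row.names = FALSE)
      art$parameters <- file.path(out_dir, "parameters.csv")
      art$summary <- write_json(list(
        model = fit$model, logLik = fit$logLik, aic = fit$aic,
        bic = fit$bic, n_params = fit$n_params,
        converged = fit$converged, seed = seed), "fit.json")
      return(invisible(list(fit = fit, artifacts = art)))
    }
    if (cmd == "tree") {
      fit <- emels_tree(fml, ld, model = config$model %||% "emels", Q = Q,
                        cp = config$cp %||% 0.001,
                        minsplit = config$minsplit %||% 20,
                        cv_folds = config$cv_folds %||% 10,
                        seed = seed)
      txt <- utils::capture.output(print(fit$tree$rpart))
      writeLines(txt, file.path(out_dir, "tree.txt"))
      art$tree <- file.path(out_dir, "tree.txt")
      art$summary <- write_json(list(
        model = fit$model, leaves = fit$tree$G,
        leaf_means = unname(fit$beta), logLik = fit$logLik,
        alternations = fit$n_alternations, seed = seed), "tree.json")
      return(invisible(list(fit = fit, artifacts = art)))
    }
    # lasso
    path <- lambda_path(fml, ld, Q = Q,
                        lambdas = config$lambdas %||%
                          seq(0, 500, length.out = 50),
                        criterion = config$criterion %||% "bic")
    utils::write.csv(path$table, file.path(out_dir, "lasso_path.csv"),
                     row.names = FALSE)
    art$path <- file.path(out_dir, "lasso_path.csv")
    art$summary <- write_json(list(
      selected = path$selected, criterion = path$criterion, seed = seed),
      "lasso.json")
    return(invisible(list(path = path, artifacts = art)))
  }

  if (cmd == "benchmark") {
    ld <- read_config_data()
    split <- split_train_test(ld, config$n_train_persons,
                              config$n_train_times)
    fml <- if (!is.null(config$formula)) stats::as.formula(config$formula)
           else NULL
    Q <- config$Q %||% 5L
    models <- config$models %||% c("mem_ar1", "emels")
    fits <- list()
    for (m in models) {
      fits[[m]] <- switch(m,
        mem_ar1 = mem_ar1(fml, split$train),
        emels = emels(fml, split$train, Q = Q),
        emels_tree = emels_tree(fml, split$train, model = "emels", Q = Q,
                                seed = seed),
        mem_tree = emels_tree(fml, split$train, model = "lmm_ar1",
                              seed = seed),
        stop("unknown model '", m, "'"))
    }
    tab <- forecast_benchmark(fits, split)
    utils::write.csv(tab, file.path(out_dir, "benchmark.csv"),
                     row.names = FALSE)
    art$benchmark <- file.path(out_dir, "benchmark.csv")
    art$summary <- write_json(list(seed = seed, models = models), "benchmark.json")
    return(invisible(list(benchmark = tab, fits = fits, artifacts = art)))
  }

  stop("unknown command '", cmd, "'")
}
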