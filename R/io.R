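#' Load a paired (y, x) dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header, extracts the study and auxiliary
#' columns, and drops rows with a missing value in either column pairwise
#' (the number of dropped rows is recorded in the provenance attribute and
#' reported via `message`).
#'
#' @param path Path to a delimited text file.
#' @param y_col,x_col Column names of the study and auxiliary variables.
#' @param sep Field separator; `NULL` (default) picks TSV for `.tsv` files
#'   and CSV otherwise.
#' @return A list with `y`, `x`, and `provenance` (path, rows read, rows
#'   dropped).
#' @export
load_dataset <- function(path, y_col = "y", x_col = "x", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- tryCatch(read.csv(path, sep = sep, stringsAsFactors = FALSE),
                 error = function(e) stop("unreadable file: ", path,
                                          " (", conditionMessage(e), ")"))
  for (cc in c(y_col, x_col))
    if (!cc %in% names(df)) stop("missing column '", cc, "' in ", path)
  if (nrow(df) < 2) stop("fewer than 2 complete rows in ", path)
  y <- df[[y_col]]; x <- df[[x_col]]
  if (!is.numeric(y) || !is.numeric(x))
    stop("non-numeric cells in columns '", y_col, "'/'", x_col, "'")
  keep <- complete.cases(y, x)
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("dropped %d row(s) with missing y or x", dropped))
  y <- y[keep]; x <- x[keep]
  if (length(y) < 2) stop("fewer than 2 complete rows in ", path)
  list(y = y, x = x,
       provenance = list(path = path, rows_read = nrow(df),
                         rows_dropped = dropped))
}

#' Write a small paired-data fixture with its known truth
#'
#' Generates a <= 200-row (y, x) dataset of a named kind, writes it as CSV,
#' and writes the exact population summary alongside as JSON so round-trip
#' tests can compare recomputed summaries against a documented truth.
#'
#' Kinds: `"linear"` (y exactly affine in x, correlation 1), `"skewed"`
#' (gamma-like positive pair), `"degenerate"` (constant x column, exercising
#' undefined-correlation paths).
#'
#' @param kind `"linear"`, `"skewed"` or `"degenerate"`.
#' @param stream An [rng_stream()].
#' @param dir Output directory (created if needed).
#' @param rows Number of rows (<= 200).
#' @return List with `csv`, `truth` (file paths) and the `summary` written.
#' @export
make_fixture <- function(kind = c("linear", "skewed", "degenerate"),
                         stream = rng_stream(1), dir = tempdir(),
                         rows = 60) {
  kind <- match.arg(kind)
  rows <- min(as.integer(rows), 200L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xy <- switch(kind,
    linear = {
      x <- seq_len(rows)
      list(y = 3 + 2 * x, x = as.numeric(x))
    },
    skewed = with_stream(stream, {
      x <- qgamma(runif(rows), shape = 2, scale = 10)
      y <- 5 + 0.6 * x + qgamma(runif(rows), shape = 2, scale = 2)
      list(y = y, x = x)
    }),
    degenerate = with_stream(stream, {
      list(y = rnorm(rows, 10, 2), x = rep(7, rows))
    }))
  csv <- file.path(dir, sprintf("fixture-%s.csv", kind))
  truth <- file.path(dir, sprintf("fixture-%s-truth.json", kind))
  write.csv(data.frame(y = xy$y, x = xy$x), csv, row.names = FALSE)
  s <- summarize_population(xy$y, xy$x)
  jsonlite::write_json(unclass(s), truth, auto_unbox = TRUE, digits = NA,
                       na = "null")
  list(csv = csv, truth = truth, summary = s)
}

#' Run a configured analysis and write its artifacts
#'
#' Executes one of the package's four modes from a configuration list (or a
#' YAML/JSON file read with [read_run_config()]) and writes CSV result tables
#' plus a JSON metadata sidecar recording the seed, mode, estimator variants,
#' theory path, quantile rule and package version, so every table is
#' reproducible from its sidecar alone.
#'
#' Modes:
#' \describe{
#'   \item{estimate}{needs `data` (path), `mu_x`, optional `estimators`,
#'     `constants`, `N`; writes one row per estimator.}
#'   \item{theory}{needs a `summary` block (population quantities) and `n`;
#'     optional `mode` (series/printed); writes bias/MSE/PRE per estimator.}
#'   \item{simulate}{needs a `scenario` block (fields of [scenario_spec()]);
#'     writes the Monte-Carlo results table.}
#'   \item{tune}{needs a `scenario` block plus `estimator` and `n`; writes
#'     the tuned constants and achieved empirical MSE.}
#' }
#'
#' @param config Named list; see Details.
#' @param out_dir Output directory.
#' @return (Invisibly) list with paths `table` and `meta`.
#' @export
run_config <- function(config, out_dir = ".") {
  stopifnot(is.list(config))
  mode <- config$mode
  if (is.null(mode) || !mode %in% c("estimate", "theory", "simulate", "tune"))
    stop("config$mode must be one of estimate/theory/simulate/tune")
  seed <- as.integer(config$seed %||% 1L)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  variant <- config$variant %||% "standard"
  theory_mode <- config$theory_mode %||% config$mode_theory %||% "series"
  tab <- switch(mode,
    estimate = {
      if (is.null(config$data)) stop("estimate mode needs config$data")
      if (is.null(config$mu_x)) stop("estimate mode needs config$mu_x")
      ds <- load_dataset(config$data,
                         y_col = config$y_col %||% "y",
                         x_col = config$x_col %||% "x")
      fit <- lrmean(y ~ x, data.frame(y = ds$y, x = ds$x),
                    mu_x = config$mu_x, N = config$N,
                    estimators = config$estimators %||%
                      c("T0", "T1", "T2", "T3", "T4", "T5", "TP1", "TP2"),
                    constants = config$constants %||% list(),
                    summary = if (!is.null(config$summary))
                      do.call(population_summary, config$summary) else NULL,
                    variant = variant)
      fit$estimates
    },
    theory = {
      if (is.null(config$summary)) stop("theory mode needs config$summary")
      if (is.null(config$n)) stop("theory mode needs config$n")
      ps <- do.call(population_summary, config$summary)
      mse_table(ps, n = config$n,
                estimators = config$estimators %||%
                  c("T0", "T1", "T2", "T3", "T4", "T5", "T6", "TP1", "TP2"),
                mode = theory_mode,
                constants = config$constants %||% list())
    },
    simulate = {
      sc <- do.call(scenario_spec,
                    c(config$scenario, list(seed = seed)))
      run_monte_carlo(sc)$results
    },
    tune = {
      if (is.null(config$estimator)) stop("tune mode needs config$estimator")
      sc <- do.call(scenario_spec, c(config$scenario, list(seed = seed)))
      stream <- rng_stream(seed)
      pop <- generate_population(sc, stream)
      tn <- empirical_tune(config$estimator, pop, n = config$n %||%
                             sc$n_list[1],
                           R_tune = sc$R_tune, stream = stream)
      data.frame(estimator = config$estimator,
                 constant = names(tn$constants),
                 value = unlist(tn$constants),
                 mse = tn$mse, status = tn$status,
                 stringsAsFactors = FALSE)
    })
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  table_path <- file.path(out_dir, sprintf("lrmean-%s.csv", mode))
  meta_path <- file.path(out_dir, sprintf("lrmean-%s-meta.json", mode))
  write.csv(tab, table_path, row.names = FALSE)
  meta <- list(mode = mode, seed = seed, variant = variant,
               theory_mode = theory_mode,
               quantile_rule = "type7-linear-interpolation",
               package_version = as.character(packageVersion("lrmean")),
               written = stamp)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$verbose))
    message(sprintf("[%s] wrote %s and %s", stamp, table_path, meta_path))
  invisible(list(table = table_path, meta = meta_path))
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file whose
#'   keys mirror the arguments documented in [run_config()].
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json")
  }
}
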