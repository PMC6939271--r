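#' Run a parameter sweep of replicate simulations
#'
#' Runs `base_config$replicates` independent replicate populations
#' ([run_replicate()]) for every row of a parameter grid and aggregates the
#' evolutionary endpoints. Each grid row may override any of `model`, `g_r`,
#' `g_e`, `n`, `alpha` (missing columns fall back to `base_config` /
#' `base_grain`). Endpoint gene statistics are computed over surviving
#' replicates only; the survival proportion is reported separately.
#'
#' Seeds derive from `(master_seed, cell, replicate)` via [child_seed()], so
#' results are deterministic given the master seed, and adding grid rows or
#' replicates never changes existing cells.
#'
#' @param base_config A [sim_config()] object with the shared lifecycle and
#'   run parameters.
#' @param params A [payoff_params()] object.
#' @param grid A data.frame whose columns are a subset of
#'   `c("model", "g_r", "g_e", "n", "alpha")`, one row per parameter
#'   combination.
#' @param base_grain A [grain_params()] object supplying grains not varied
#'   by the grid.
#' @param verbose If `TRUE`, report per-cell progress on standard error.
#' @return An `experiment_result` data.frame with one row per grid cell:
#'   the cell's parameters (`model`, `g_r`, `g_e`, `n`, `alpha`, `a`, `b`,
#'   `mu`, `K`, `m_p`, `m_sigma`, `seasons`), `replicates_run`,
#'   `mean_final_gene` and `sd_final_gene` (over surviving replicates;
#'   `NA` if none survived) and `survival_proportion`.
#' @examples
#' cfg <- sim_config(K = 50, seasons = 20, replicates = 2, master_seed = 7)
#' grid <- expand.grid(g_r = c(0, 1), n = c(1L, 5L))
#' run_sweep(cfg, payoff_params(), grid)
#' @export
run_sweep <- function(base_config, params, grid,
                      base_grain = grain_params(), verbose = FALSE) {
  stopifnot(inherits(base_config, "sim_config"),
            inherits(params, "payoff_params"),
            inherits(base_grain, "grain_params"),
            is.data.frame(grid))
  if (nrow(grid) == 0L) stop("'grid' must have at least one row", call. = FALSE)
  allowed <- c("model", "g_r", "g_e", "n", "alpha")
  bad <- setdiff(names(grid), allowed)
  if (length(bad))
    stop("unknown grid column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  cell_value <- function(col, row, default)
    if (col %in% names(grid)) grid[[col]][row] else default

  rows <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$model <- as.character(cell_value("model", cell, base_config$model))
    cfg$n <- as.integer(cell_value("n", cell, base_config$n))
    cfg$alpha <- cell_value("alpha", cell, base_config$alpha)
    grain <- grain_params(g_r = cell_value("g_r", cell, base_grain$g_r),
                          g_e = cell_value("g_e", cell, base_grain$g_e))
    if (verbose)
      message(sprintf("cell %d/%d: model=%s g_r=%g g_e=%g n=%d alpha=%g",
                      cell, nrow(grid), cfg$model, grain$g_r, grain$g_e,
                      cfg$n, cfg$alpha))
    reps <- lapply(seq_len(cfg$replicates), function(r)
      run_replicate(cfg, grain, params,
                    seed = child_seed(cfg$master_seed, cell, r),
                    replicate_id = r))
    survived <- vapply(reps, `[[`, logical(1), "survived")
    finals <- vapply(reps, `[[`, numeric(1), "final_mean_gene")[survived]
    rows[[cell]] <- data.frame(
      model = cfg$model, g_r = grain$g_r, g_e = grain$g_e,
      n = cfg$n, alpha = cfg$alpha,
      a = params$a, b = params$b, mu = params$mu,
      K = cfg$K, m_p = cfg$m_p, m_sigma = cfg$m_sigma,
      seasons = cfg$seasons,
      replicates_run = cfg$replicates,
      mean_final_gene = if (length(finals)) mean(finals) else NA_real_,
      sd_final_gene = if (length(finals) > 1L) stats::sd(finals) else NA_real_,
      survival_proportion = mean(survived),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "master_seed") <- base_config$master_seed
  class(out) <- c("experiment_result", "data.frame")
  out
}

#' Columns of an experiment result table, in their documented order
#' @return Character vector of column names.
#' @export
experiment_columns <- function() {
  c("model", "g_r", "g_e", "n", "alpha", "a", "b", "mu", "K", "m_p",
    "m_sigma", "seasons", "replicates_run", "mean_final_gene",
    "sd_final_gene", "survival_proportion")
}

#' Write an experiment result to CSV (with a JSON metadata sidecar)
#'
#' Writes the long-format result table, one row per parameter combination,
#' with the documented column order and full floating-point precision (17
#' significant digits, so a read-back reproduces the table exactly). A JSON
#' sidecar `<path>.json` records the master seed, package version and
#' timestamp.
#'
#' @param result An `experiment_result` from [run_sweep()].
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @seealso [read_experiment()]
#' @export
write_experiment <- function(result, path, sidecar = TRUE) {
  stopifnot(is.data.frame(result),
            all(experiment_columns() %in% names(result)))
  out <- result[, experiment_columns()]
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  if (sidecar) {
    meta <- list(master_seed = attr(result, "master_seed"),
                 package_version = as.character(
                   utils::packageVersion("bethedge")),
                 written = format(Sys.time(), tz = "UTC", usetz = TRUE),
                 columns = experiment_columns())
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back an experiment result CSV
#'
#' Inverse of [write_experiment()]: restores column types and the
#' `experiment_result` class (and the master seed, if the sidecar is
#' present).
#'
#' @param path CSV path written by [write_experiment()].
#' @return An `experiment_result` data.frame.
#' @export
read_experiment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(experiment_columns() %in% names(df)))
  for (col in c("n", "K", "seasons", "replicates_run"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("g_r", "g_e", "alpha", "a", "b", "mu", "m_p", "m_sigma",
                "mean_final_gene", "sd_final_gene", "survival_proportion"))
    df[[col]] <- as.numeric(df[[col]])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$master_seed))
      attr(df, "master_seed") <- as.integer(meta$master_seed)
  }
  class(df) <- c("experiment_result", "data.frame")
  df
}

#' Plot evolved gene values across a grain gradient
#'
#' Endpoint summary figure: mean evolved gene value (+/- one
#' across-replicate SD) against a grain parameter, one colour per number of
#' decision events `n`, point size showing the proportion of replicate
#' populations surviving.
#'
#' @param result An `experiment_result` from [run_sweep()].
#' @param x Which grain to put on the x-axis: `"g_r"` (default) or `"g_e"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(result, x = c("g_r", "g_e")) {
  x <- match.arg(x)
  stopifnot(is.data.frame(result))
  df <- as.data.frame(result)
  df$n <- factor(df$n)
  df$.x <- df[[x]]
  ggplot2::ggplot(df, ggplot2::aes(x = .x, y = mean_final_gene,
                                   colour = n, group = n)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_final_gene - sd_final_gene,
                                        ymax = mean_final_gene + sd_final_gene),
                           width = 0.03) +
    ggplot2::geom_point(ggplot2::aes(size = survival_proportion)) +
    ggplot2::scale_size_continuous(limits = c(0, 1), range = c(0.5, 3)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = x, y = "mean evolved gene value",
                  colour = "events n", size = "survival") +
    ggplot2::theme_minimal()
}
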