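#' Run the end-to-end pipeline: simulate, quantify, or both
#'
#' Orchestrates a whole experiment from one configuration: \code{mode =
#' "simulate"} generates synthetic fragment stacks (with ground truth and a
#' layout file), \code{"quantify"} classifies existing stacks and emits
#' trajectory, fold-increase and statistics tables, and \code{"full"} chains
#' both and additionally writes a recovered-vs-true comparison. All numeric
#' outputs are CSVs; identical config + seed gives byte-identical CSVs. A
#' single global seed feeds every stochastic stage through derived
#' per-fragment streams and is recorded in the manifest.
#'
#' Configuration (YAML file or list):
#' \preformatted{
#' seed: 1
#' experiment:
#'   tumor_model: MC38
#'   conditions: [isotype, anti_PD1, anti_CTLA4]
#'   fragments_per_condition: 3
#' simulation:           # any simulation_params() argument
#'   fragment_diameter: 200
#' thresholds:           # required for quantify/full
#'   live_green: 600
#'   til_red: 1100
#'   dead_apc: 1100
#'   min_area: 100       # um^2
#'   connectivity: 8
#'   mode: slice
#' quantify:
#'   denominator: green_tumor
#'   control_condition: isotype
#'   plot: true
#' layout: path/to/layout.yaml   # quantify mode only; full/simulate use out_dir
#' }
#'
#' @param config YAML path or list.
#' @param mode one of \code{"full"}, \code{"simulate"}, \code{"quantify"}.
#' @param out_dir output directory (created if needed).
#' @param seed integer; overrides \code{config$seed} (default 1).
#' @param log_level \code{"info"}, \code{"quiet"} or \code{"debug"}.
#' @return invisibly, the run manifest (also written as
#'   \code{manifest.json}): mode, seed, package version, config hash, and
#'   every output file written. Partial outputs are removed on failure.
#' @export
run_pipeline <- function(config, mode = c("full", "simulate", "quantify"),
                         out_dir, seed = NULL,
                         log_level = c("info", "quiet", "debug")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML path or a list")
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say <- function(...) if (log_level != "quiet") message("[tilkill] ", ...)
  created <- character(0)
  note <- function(path) { created <<- c(created, path); path }

  result <- tryCatch({
    # normalized config copy; its md5 is the config hash
    cfg_path <- note(file.path(out_dir, "config.json"))
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)

    layout <- NULL
    if (mode %in% c("simulate", "full")) {
      say("simulating fragments (seed ", seed, ")")
      layout <- pipeline_simulate(config, out_dir, seed, note, say)
    }
    tables <- NULL
    if (mode %in% c("quantify", "full")) {
      if (is.null(layout)) {
        lp <- config$layout %||%
          stop_config("quantify mode needs config$layout (a layout YAML path)")
        layout <- load_layout(lp)
      }
      say("quantifying ", nrow(layout$fragments), " fragments")
      tables <- pipeline_quantify(config, layout, out_dir, note, say,
                                  with_truth = (mode == "full"))
    }

    manifest <- list(
      mode = mode, seed = seed,
      package_version = as.character(utils::packageVersion("tilkill")),
      config_hash = unname(tools::md5sum(cfg_path)),
      files = sort(unique(sub(paste0("^", out_dir, "/?"), "", created))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("wrote ", length(manifest$files) + 1L, " files to ", out_dir)
    manifest
  }, error = function(e) {
    suppressWarnings(file.remove(created[file.exists(created)]))
    stop(e)
  })
  invisible(result)
}

pipeline_simulate <- function(config, out_dir, seed, note, say) {
  exp_cfg <- config$experiment %||% list()
  conditions <- unlist(exp_cfg$conditions) %||% TK_CONDITIONS
  bad <- setdiff(conditions, TK_CONDITIONS)
  if (length(bad))
    stop_config("unknown condition(s) in config: ",
                paste(bad, collapse = ", "))
  n_per <- exp_cfg$fragments_per_condition %||% 3L
  model <- exp_cfg$tumor_model %||% "synthetic"

  sim_cfg <- config$simulation %||% list()
  base_args <- sim_cfg[intersect(names(sim_cfg),
                                 names(formals(simulation_params)))]
  extra <- setdiff(names(sim_cfg), names(formals(simulation_params)))
  if (length(extra))
    stop_config("unknown simulation parameter(s): ",
                paste(extra, collapse = ", "))

  n_frag <- length(conditions) * n_per
  frag_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_frag))

  stack_dir <- file.path(out_dir, "stacks")
  dir.create(stack_dir, showWarnings = FALSE)

  sims <- list()
  frag_rows <- list()
  stack_rows <- list()
  i <- 0L
  for (cond in conditions) for (j in seq_len(n_per)) {
    i <- i + 1L
    fid <- sprintf("%s_%02d", cond, j)
    p <- do.call(simulation_params, c(base_args, list(seed = frag_seeds[i])))
    p <- apply_condition(p, cond)
    say("  ", fid)
    sim <- simulate_fragment(p, fragment_id = fid)
    sims[[fid]] <- sim
    for (kk in seq_along(sim$stacks)) {
      rel <- file.path("stacks", sprintf("%s_t%03d.tif", fid, kk))
      path <- file.path(out_dir, rel)
      write_stack(sim$stacks[[kk]], path)
      note(path); note(paste0(path, ".json"))
      stack_rows[[length(stack_rows) + 1L]] <-
        data.frame(fragment_id = fid, time_h = sim$stacks[[kk]]$time_h,
                   path = rel, stringsAsFactors = FALSE)
    }
    frag_rows[[i]] <- data.frame(fragment_id = fid, condition = cond,
                                 tumor_model = model, stringsAsFactors = FALSE)
  }

  tp <- sims[[1]]$params$time_points
  stacks <- do.call(rbind, stack_rows)
  raw <- list(
    time_points = tp,
    conditions = conditions,
    fragments = lapply(seq_len(n_frag), function(ii) {
      fid <- frag_rows[[ii]]$fragment_id
      st <- stacks[stacks$fragment_id == fid, ]
      list(fragment_id = fid, condition = frag_rows[[ii]]$condition,
           tumor_model = model,
           stacks = stats::setNames(as.list(st$path),
                                    format(st$time_h, trim = TRUE)))
    }))
  layout_path <- note(file.path(out_dir, "layout.yaml"))
  yaml::write_yaml(raw, layout_path)

  write_truth_csv(sims, note(file.path(out_dir, "truth.csv")))
  load_layout(layout_path)
}

pipeline_quantify <- function(config, layout, out_dir, note, say,
                              with_truth = FALSE) {
  missing <- layout_missing_paths(layout)
  if (length(missing))
    stop_config("stack file(s) missing before processing: ",
                paste(missing, collapse = ", "))

  th_cfg <- config$thresholds %||%
    stop_config("config$thresholds is required (one per channel; the ",
                "pipeline never applies automatic thresholds silently)")
  th_missing <- setdiff(TK_CHANNELS, names(th_cfg))
  if (length(th_missing))
    stop_config("missing threshold(s) for channel(s): ",
                paste(th_missing, collapse = ", "))
  cfg <- threshold_config(
    thresholds = unlist(th_cfg[TK_CHANNELS]),
    min_area = th_cfg$min_area %||% 0,
    connectivity = th_cfg$connectivity,
    mode = th_cfg$mode %||% "slice")

  q <- config$quantify %||% list()
  denom <- q$denominator %||% "green_tumor"
  control <- q$control_condition %||% "isotype"

  records <- list()
  records_total <- list()
  for (i in seq_len(nrow(layout$stacks))) {
    st <- read_stack(layout$stacks$path[i], layout$stacks$sidecar[i])
    cv <- classify_stack(st, cfg)
    records[[i]] <- dying_fraction(cv, denominator = denom)
    if (with_truth)
      records_total[[i]] <- dying_fraction(cv, denominator = "all_tumor")
  }
  records <- do.call(rbind, records)
  write.csv(records, note(file.path(out_dir, "records.csv")),
            row.names = FALSE)

  ts <- dying_timeseries(records, layout)
  write.csv(ts$fragments, note(file.path(out_dir, "trajectory.csv")),
            row.names = FALSE)
  write.csv(ts$conditions, note(file.path(out_dir, "condition_summary.csv")),
            row.names = FALSE)

  folds <- fold_increase_table(ts$conditions, control_condition = control)
  if (!nrow(folds) &&
      length(setdiff(unique(layout$fragments$condition), control)) == 0)
    warning("no treated condition in the layout; fold-increase table is empty")
  write.csv(folds, note(file.path(out_dir, "fold_increase.csv")),
            row.names = FALSE)

  kw <- kruskal_by_day(ts$fragments, value_col = "dying_fraction",
                       group_col = "condition", day_col = "time_h")
  write.csv(kw, note(file.path(out_dir, "kruskal_wallis.csv")),
            row.names = FALSE)

  if (isTRUE(q$plot %||% TRUE)) {
    pl <- plot_dying_timeseries(ts$conditions, kw = kw)
    pdf_path <- note(file.path(out_dir, "trajectory_plot.pdf"))
    grDevices::pdf(pdf_path, width = 6, height = 4)
    print(pl)
    grDevices::dev.off()
  }

  out <- list(records = records, timeseries = ts, folds = folds, kw = kw)

  if (with_truth) {
    truth <- read.csv(file.path(out_dir, "truth.csv"))
    rec_total <- do.call(rbind, records_total)
    cmp <- merge(truth[c("fragment_id", "time_h", "true_fraction")],
                 rec_total[c("fragment_id", "time_h", "dying_fraction")],
                 by = c("fragment_id", "time_h"))
    names(cmp)[names(cmp) == "dying_fraction"] <- "recovered_fraction"
    cmp$abs_error <- abs(cmp$recovered_fraction - cmp$true_fraction)
    cmp <- cmp[order(cmp$fragment_id, cmp$time_h), ]
    write.csv(cmp, note(file.path(out_dir, "recovery.csv")),
              row.names = FALSE)
    out$recovery <- cmp
  }
  out
}
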