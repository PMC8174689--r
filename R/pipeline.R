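.stages <- c("generate", "observables", "tails", "cluster", "crosstab",
             "report")

# one global seed fans out to deterministic per-stage seeds (< 2^31)
.stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 65011L) * 33013L + match(stage, .stages)
}

.log <- function(..., level = "INFO", min_level = "INFO") {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[level] < levels[min_level]) return(invisible())
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

#' Read a pipeline run configuration
#'
#' Configurations are YAML (or JSON) with exactly one of `synthetic` (a
#' breathing scenario plus optional [synthetic_spec()] overrides) or `input`
#' (topology + trajectory paths with an annotation `profile`), and optional
#' `seed`, `opening_arm`, `strides` (`angles`, `contacts`), `clustering`
#' (`k`, `selections`), `tails` and `output_dir` entries.
#'
#' @param config list or path to a YAML/JSON file
#' @return validated config list
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "output_dir", "synthetic", "input", "profile",
             "opening_arm", "strides", "clustering", "tails",
             "frame_interval_ps", "log_level")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$input)
  if (has_syn == has_inp)
    stop("config must name exactly one of 'synthetic' or 'input'")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$opening_arm)) config$opening_arm <- "3p"
  if (is.null(config$strides)) config$strides <- list()
  if (is.null(config$strides$angles)) config$strides$angles <- 1L
  if (is.null(config$strides$contacts)) config$strides$contacts <- 5L
  if (any(unlist(config$strides) < 1)) stop("strides must be >= 1")
  if (is.null(config$clustering)) config$clustering <- list()
  if (is.null(config$clustering$k)) config$clustering$k <- 8L
  if (is.null(config$clustering$selections))
    config$clustering$selections <- c("dna", "h3", "h2ac")
  if (is.null(config$log_level)) config$log_level <- "INFO"
  config
}

.build_synthetic <- function(config) {
  syn <- config$synthetic
  spec_args <- if (is.null(syn$spec)) list() else syn$spec
  if (is.null(spec_args$seed)) spec_args$seed <- .stage_seed(config$seed,
                                                             "generate")
  spec <- do.call(synthetic_spec, spec_args)
  sc_args <- syn[setdiff(names(syn), c("spec", "scenario"))]
  sc_args$scenario <- if (is.null(syn$scenario)) "constant" else syn$scenario
  sc <- do.call(breathing_scenario, sc_args)
  fi <- if (is.null(config$frame_interval_ps)) 20 else config$frame_interval_ps
  make_breathing_trajectory(spec, sc$angles, sc$tails,
                            seed = spec$seed, frame_interval_ps = fi)
}

.load_input <- function(config) {
  topo <- read_structure(config$input$topology)
  fi <- if (is.null(config$input$frame_interval_ps)) 20
        else config$input$frame_interval_ps
  traj <- read_trajectory(topo, config$input$trajectory,
                          frame_interval_ps = fi)
  prof <- if (is.null(config$profile)) "human" else config$profile
  ann <- annotate_nucleosome(topo, prof, opening_arm = config$opening_arm)
  list(trajectory = traj, annotation = ann, ground_truth = NULL)
}

#' Run the full breathing-analysis pipeline
#'
#' Stages: generate (or load) the trajectory, compute breathing observables
#' (opening angles, DNA Rg, gamma histograms), tail configuration series,
#' conformational k-means clustering per selection, DNA-to-tail co-occupancy
#' matrices, and a 5-95 percentile report. All outputs are CSV/JSON files
#' with deterministic names in `output_dir`; a manifest records the config,
#' seeds, row counts and checksums. Rerunning with an identical config
#' reproduces identical outputs.
#'
#' @param config run configuration (list or YAML path, see
#'   [read_run_config()])
#' @param output_dir overrides the config's output directory
#' @return the manifest list, invisibly; all file paths in
#'   `manifest$outputs`
#' @export
run_analysis <- function(config, output_dir = NULL) {
  config <- read_run_config(config)
  dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  if (is.null(dir)) stop("no output directory given")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lvl <- config$log_level
  outputs <- character(0)
  counts <- list()
  run_stage <- function(stage, fn) {
    .log("stage ", stage, " ...", min_level = lvl)
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$synthetic)) {
    gen <- run_stage("generate", function() .build_synthetic(config))
    run_stage("generate", function() {
      write_structure(gen$trajectory$topology, file.path(dir, "structure.pdb"))
      write_trajectory(gen$trajectory, file.path(dir, "trajectory.dcd"))
      write_ground_truth_json(gen$ground_truth,
                              file.path(dir, "ground_truth.json"))
      write_annotation_json(gen$annotation, file.path(dir, "annotation.json"))
    })
    outputs <- c(outputs, file.path(dir, c("structure.pdb", "trajectory.dcd",
                                           "ground_truth.json",
                                           "annotation.json")))
  } else {
    gen <- run_stage("generate", function() .load_input(config))
  }
  traj <- gen$trajectory
  ann <- gen$annotation

  obs <- run_stage("observables", function() {
    s <- breathing_series(traj, ann, stride = config$strides$angles)
    write_series_csv(s, file.path(dir, "angles.csv"))
    for (arm in c("3p", "5p")) {
      h <- gamma_histogram2d(s, arm)
      jsonlite::write_json(
        list(arm = arm, bin_width = h$bin_width,
             occupied_area = h$occupied_area,
             mode_bin = as.list(h$mode_bin), n_frames = h$n_frames),
        file.path(dir, paste0("gamma_hist_", arm, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    s
  })
  outputs <- c(outputs, file.path(dir, c("angles.csv", "gamma_hist_3p.json",
                                         "gamma_hist_5p.json")))
  counts$angles <- nrow(obs)

  tail_ids <- config$tails
  if (is.null(tail_ids) && !is.null(ann$tails))
    tail_ids <- intersect(c("H3_3p", "H3_5p", "H2AC_3p", "H2AC_5p"),
                          ann$tails$tail_id)
  tail_series <- list()
  run_stage("tails", function() {
    for (id in tail_ids) {
      ts <- tail_configuration_series(traj, ann, id,
                                      stride = config$strides$contacts)
      write_series_csv(ts, file.path(dir, paste0("tail_", id, ".csv")))
      tail_series[[id]] <<- ts
    }
  })
  outputs <- c(outputs, file.path(dir, paste0("tail_", tail_ids, ".csv")))
  counts$tails <- vapply(tail_series, nrow, 1L)

  models <- list()
  run_stage("cluster", function() {
    sel_tags <- config$clustering$selections
    lab <- NULL
    for (tag in sel_tags) {
      fm <- build_feature_matrix(traj, ann, tag)
      models[[tag]] <<- kmeans_cluster(
        fm, k = config$clustering$k,
        seed = .stage_seed(config$seed, "cluster"), selection_tag = tag)
      col <- data.frame(models[[tag]]$assignment)
      names(col) <- paste0(tag, "_cluster")
      lab <- if (is.null(lab)) cbind(data.frame(frame = attr(fm, "frames")),
                                     col) else cbind(lab, col)
    }
    write_series_csv(lab, file.path(dir, "clusters.csv"))
  })
  outputs <- c(outputs, file.path(dir, "clusters.csv"))
  counts$clusters <- length(models[[1]]$assignment)

  run_stage("crosstab", function() {
    if (!"dna" %in% names(models)) return()
    for (tag in setdiff(names(models), "dna")) {
      ct <- cross_tabulate(models$dna, models[[tag]])
      utils::write.csv(as.data.frame(unclass(ct)),
                       file.path(dir, paste0("crosstab_dna_", tag, ".csv")))
      outputs <<- c(outputs, file.path(dir,
                                       paste0("crosstab_dna_", tag, ".csv")))
    }
    gm <- map_clusters_to_gamma(models$dna, obs, ann$opening_arm)
    write_series_csv(gm, file.path(dir, "cluster_gamma_dna.csv"))
    outputs <<- c(outputs, file.path(dir, "cluster_gamma_dna.csv"))
  })

  run_stage("report", function() {
    rows <- list(
      percentile_summary(obs$rg, label = "dna_rg"),
      percentile_summary(obs$gamma1_3p, label = "gamma1_3p"),
      percentile_summary(obs$gamma2_3p, label = "gamma2_3p"),
      percentile_summary(obs$gamma1_5p, label = "gamma1_5p"),
      percentile_summary(obs$gamma2_5p, label = "gamma2_5p"))
    for (id in names(tail_series)) {
      ts <- tail_series[[id]]
      rows <- c(rows, list(
        percentile_summary(ts$nc_outer, label = paste0("nc_outer_", id)),
        percentile_summary(ts$delta_ldna, label = paste0("delta_ldna_", id))))
    }
    write_series_csv(do.call(rbind, rows), file.path(dir, "summary.csv"))
  })
  outputs <- c(outputs, file.path(dir, "summary.csv"))

  manifest <- list(
    package = "nucbreathe",
    version = as.character(utils::packageVersion("nucbreathe")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(.stages, function(s) .stage_seed(config$seed, s)), .stages),
    config = config[setdiff(names(config), "output_dir")],
    row_counts = counts,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(outputs))), basename(outputs)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  .log("run complete: ", length(outputs), " output file(s) in ", dir,
       min_level = lvl)
  invisible(manifest)
}

# ---- command-line interface -------------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: nucbreathe <subcommand> [--config PATH] [--seed INT]",
    "                  [--stride INT] [--out DIR] [--log-level LEVEL]",
    "",
    "subcommands:",
    "  run          full pipeline: generate/load, observables, tails,",
    "               cluster, crosstab, report",
    "  generate     generator stage only (writes structure/trajectory/",
    "               ground truth/annotation)",
    "  observables  angles/Rg series + gamma histograms from stage files",
    "  cluster      k-means clustering from stage files",
    "  crosstab     co-occupancy matrices from clusters.csv",
    "  report       percentile summary from stage files",
    "  --version    print version and exit",
    sep = "\n")
}

.cli_parse <- function(args) {
  out <- list(subcommand = NULL, config = NULL, seed = NULL, stride = NULL,
              out = NULL, log_level = "INFO")
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--version") { out$version <- TRUE; i <- i + 1L; next }
    if (a %in% c("--config", "--seed", "--stride", "--out", "--log-level")) {
      if (i == length(args)) stop("missing value for ", a)
      key <- sub("^--", "", a)
      key <- sub("-", "_", key, fixed = TRUE)
      out[[key]] <- args[i + 1L]
      i <- i + 2L
      next
    }
    if (grepl("^-", a)) stop("unknown flag: ", a)
    if (!is.null(out$subcommand)) stop("multiple subcommands given: ",
                                       out$subcommand, ", ", a)
    out$subcommand <- a
    i <- i + 1L
  }
  out
}

# rebuild trajectory + annotation from a generate-stage output directory
.cli_load_stage <- function(dir) {
  topo <- read_structure(file.path(dir, "structure.pdb"))
  traj <- read_trajectory(topo, file.path(dir, "trajectory.dcd"))
  ann <- read_annotation_json(file.path(dir, "annotation.json"))
  list(trajectory = traj, annotation = ann)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over [run_analysis()] and its stages; the
#' installed `exec/nucbreathe` script forwards `commandArgs(TRUE)` here.
#' Exit codes: 0 (ok), 1 (usage error), 2 (runtime error).
#'
#' @param args character vector of command-line arguments
#' @return integer exit status, invisibly
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(.cli_parse(args), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("error: ", conditionMessage(parsed), "\n\n", .cli_usage())
    return(invisible(1L))
  }
  if (isTRUE(parsed$version)) {
    cat("nucbreathe ", as.character(utils::packageVersion("nucbreathe")),
        "\n", sep = "")
    return(invisible(0L))
  }
  if (is.null(parsed$subcommand)) {
    message(.cli_usage())
    return(invisible(1L))
  }
  if (!parsed$subcommand %in% c("run", .stages)) {
    message("error: unknown subcommand '", parsed$subcommand, "'\n\n",
            .cli_usage())
    return(invisible(1L))
  }
  status <- tryCatch({
    cfg <- if (!is.null(parsed$config)) read_run_config(parsed$config)
           else NULL
    if (!is.null(cfg)) {
      if (!is.null(parsed$seed)) cfg$seed <- as.integer(parsed$seed)
      if (!is.null(parsed$stride))
        cfg$strides$angles <- cfg$strides$contacts <-
          as.integer(parsed$stride)
      cfg$log_level <- parsed$log_level
    }
    dir <- if (!is.null(parsed$out)) parsed$out else cfg$output_dir
    if (is.null(dir)) stop("no output directory (--out or config output_dir)")
    sub <- parsed$subcommand
    if (sub %in% c("run", "generate", "observables", "tails") &&
        is.null(cfg))
      stop("subcommand '", sub, "' requires --config")
    if (sub == "run") {
      run_analysis(cfg, output_dir = dir)
    } else if (sub == "generate") {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      gen <- .build_synthetic(cfg)
      write_structure(gen$trajectory$topology, file.path(dir, "structure.pdb"))
      write_trajectory(gen$trajectory, file.path(dir, "trajectory.dcd"))
      write_ground_truth_json(gen$ground_truth,
                              file.path(dir, "ground_truth.json"))
      write_annotation_json(gen$annotation, file.path(dir, "annotation.json"))
    } else if (sub == "observables") {
      stg <- .cli_load_stage(dir)
      stride <- if (is.null(parsed$stride)) cfg$strides$angles
                else as.integer(parsed$stride)
      s <- breathing_series(stg$trajectory, stg$annotation, stride = stride)
      write_series_csv(s, file.path(dir, "angles.csv"))
    } else if (sub == "cluster") {
      stg <- .cli_load_stage(dir)
      seed <- if (!is.null(parsed$seed)) as.integer(parsed$seed)
              else if (!is.null(cfg)) .stage_seed(cfg$seed, "cluster") else 1L
      k <- if (!is.null(cfg)) cfg$clustering$k else 8L
      lab <- NULL
      for (tag in c("dna", "h3", "h2ac")) {
        fm <- build_feature_matrix(stg$trajectory, stg$annotation, tag)
        m <- kmeans_cluster(fm, k = k, seed = seed, selection_tag = tag)
        col <- data.frame(m$assignment)
        names(col) <- paste0(tag, "_cluster")
        lab <- if (is.null(lab))
          cbind(data.frame(frame = attr(fm, "frames")), col)
        else cbind(lab, col)
      }
      write_series_csv(lab, file.path(dir, "clusters.csv"))
    } else if (sub == "crosstab") {
      lab <- read_series_csv(file.path(dir, "clusters.csv"))
      for (tag in c("h3", "h2ac")) {
        col <- paste0(tag, "_cluster")
        if (!col %in% names(lab)) next
        ct <- cross_tabulate(lab$dna_cluster, lab[[col]])
        utils::write.csv(as.data.frame(unclass(ct)),
                         file.path(dir, paste0("crosstab_dna_", tag, ".csv")))
      }
    } else if (sub == "report") {
      s <- read_series_csv(file.path(dir, "angles.csv"))
      rows <- list(percentile_summary(s$rg, label = "dna_rg"))
      for (col in grep("^gamma", names(s), value = TRUE))
        rows <- c(rows, list(percentile_summary(s[[col]], label = col)))
      write_series_csv(do.call(rbind, rows), file.path(dir, "summary.csv"))
    } else if (sub == "tails") {
      stg <- .cli_load_stage(dir)
      ids <- if (!is.null(cfg$tails)) cfg$tails
             else intersect(c("H3_3p", "H3_5p", "H2AC_3p", "H2AC_5p"),
                            stg$annotation$tails$tail_id)
      for (id in ids) {
        ts <- tail_configuration_series(stg$trajectory, stg$annotation, id,
                                        stride = cfg$strides$contacts)
        write_series_csv(ts, file.path(dir, paste0("tail_", id, ".csv")))
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
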