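# Orchestration: staged pipelines driven by a YAML/list config, with
# deterministic per-stage seed derivation and a run manifest.

# deterministic 31-bit seed from (global seed, stage name): adding stages
# never perturbs the seed stream of other stages
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1048573
  (abs(as.integer(global_seed)) %% 1000003L) * 2048L + as.integer(h) %% 2048L
}

.pipeline_stages <- c("synth", "simulate", "classify", "randomize", "stats", "sizestats")

#' Validate a pipeline configuration
#'
#' A config is a list (or YAML file) with `seed`, `outdir` and `stages`
#' (a list of blocks, each with a `stage` name and its parameters). File
#' inputs must exist or be declared as outputs of an earlier stage;
#' violations are reported with the offending key named, before any stage
#' runs.
#'
#' @param config list or path to a YAML file.
#' @return the normalized config (invisibly errors otherwise).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("seed", "outdir", "stages")) {
    if (is.null(config[[key]])) stop("config error: missing key '", key, "'")
  }
  produced <- character(0)
  for (i in seq_along(config$stages)) {
    blk <- config$stages[[i]]
    if (is.null(blk$stage)) stop("config error: stages[[", i, "]] missing key 'stage'")
    if (!blk$stage %in% .pipeline_stages)
      stop("config error: unknown stage '", blk$stage, "'")
    input_keys <- switch(blk$stage,
      classify = c("table", "threshold_from"),
      stats = c("tissue", "table"),
      randomize = "tissue",
      sizestats = "tables",
      character(0))
    for (key in intersect(input_keys, names(blk))) {
      for (f in unlist(blk[[key]])) {
        if (!file.exists(f) && !(f %in% produced))
          stop("config error: stages[[", i, "]] key '", key, "': input '", f,
               "' does not exist and is not produced by an earlier stage")
      }
    }
    produced <- c(produced, unlist(blk$outputs))
  }
  invisible(config)
}

#' Run a staged pipeline
#'
#' Executes the configured stages in order and writes a run manifest
#' (`manifest.json` in `outdir`) recording the package version, per-stage
#' derived seeds, and md5 hashes of every output file. Identical configs
#' and seeds give byte-identical manifests apart from the timestamp field.
#'
#' @param config list or path to a YAML config file; see
#'   [validate_config()] and the configs under
#'   `system.file("configs", package = "giantcell")`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "giantcell",
                   version = as.character(utils::packageVersion("giantcell")),
                   global_seed = config$seed, stages = list())
  status <- "complete"
  for (blk in config$stages) {
    seed <- derive_seed(config$seed, blk$stage)
    rec <- list(stage = blk$stage, seed = seed)
    res <- tryCatch(run_stage(blk, seed, config$outdir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
      manifest$stages[[length(manifest$stages) + 1L]] <- rec
      status <- "partial"
      break
    }
    rec$outputs <- lapply(unname(as.list(res)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
    manifest$stages[[length(manifest$stages) + 1L]] <- rec
  }
  manifest$status <- status
  out <- file.path(config$outdir, "manifest.json")
  body <- manifest
  jsonlite::write_json(body, out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  # timestamp kept out of the hashed body for reproducibility checks
  invisible(manifest)
}

# execute one stage block; returns character vector of output files
run_stage <- function(blk, seed, outdir) {
  pth <- function(f) file.path(outdir, f)
  switch(blk$stage,
    synth = {
      spec <- synth_spec(n_cells = blk$n_cells %||% 150,
                         width = blk$width %||% 128, height = blk$height %||% 128,
                         pixel_size = blk$pixel_size %||% 1,
                         tail_fraction = blk$tail_fraction %||% 0.03,
                         n_stomata = blk$n_stomata %||% 0,
                         pattern = blk$pattern %||% "random", seed = seed)
      g <- generate_tissue(spec)
      tf <- pth(blk$out %||% "tissue.csv"); cf <- pth(blk$table %||% "cells.csv")
      save_tissue(g$tissue, tf)
      write_cell_table(g$table, cf)
      c(tissue = tf, table = cf)
    },
    simulate = {
      prm <- sim_params(seed = seed, t_end = blk$t_end %||% 135)
      snaps <- unlist(blk$snapshot_times) %||% numeric(0)
      out <- run_simulation(prm, snapshot_times = snaps)
      files <- character(0)
      emit <- function(state, tag) {
        sn <- sim_snapshot(state, crop = isTRUE(blk$crop))
        tf <- pth(sprintf("sim_%s_tissue.csv", tag))
        cf <- pth(sprintf("sim_%s_cells.csv", tag))
        save_tissue(sn$tissue, tf)
        write.csv(sn$table, cf, row.names = FALSE)
        c(tf, cf)
      }
      for (nm in names(out$snapshots))
        files <- c(files, emit(out$snapshots[[nm]], paste0("t", nm)))
      files <- c(files, emit(out$final, "final"))
      as.list(files)
    },
    classify = {
      tab <- read_cell_table(blk$table)
      thr <- NULL
      if (!is.null(blk$threshold_from)) {
        areas <- unlist(lapply(unlist(blk$threshold_from), function(f) {
          rt <- read_cell_table(f)
          rt$area_um2[is.na(rt$cell_type) | rt$cell_type != "stoma"]
        }))
        thr <- giant_size_threshold(areas, blk$percentile %||% 99.3)
      }
      typed <- assign_types(tab, threshold = thr,
                            classifier = rule_classifier(
                              area_cap = blk$stoma_area_cap %||% 150,
                              circularity_floor = blk$stoma_circularity_floor %||% 0.7))
      out <- pth(blk$out %||% "typed.csv")
      write_cell_table(typed, out)
      c(typed = out)
    },
    randomize = {
      tis <- load_tissue(blk$tissue, blk$pixel_size %||% 1)
      spec <- randomization_spec(
        n_random = blk$n_random %||% 400,
        orient_range = if (!is.null(blk$orient_limit))
          c(-blk$orient_limit, blk$orient_limit) else c(-pi, pi),
        fix_border = !isTRUE(blk$whole_tissue),
        fix_background = isTRUE(blk$whole_tissue),
        seed = seed)
      rd <- pth(blk$out %||% "rand")
      dir.create(rd, showWarnings = FALSE)
      files <- vapply(seq_len(spec$n_random), function(k) {
        f <- file.path(rd, sprintf("rand_%04d.csv", k))
        save_tissue(randomize_tissue(tis, spec, k), f)
        f
      }, "")
      as.list(files)
    },
    stats = {
      tis <- load_tissue(blk$tissue, blk$pixel_size %||% 1)
      typed <- read_cell_table(blk$table)
      giants <- giant_ids(typed)
      spec <- randomization_spec(n_random = blk$n_random %||% 100, seed = seed)
      res <- pooled_randomization_test(list(tis), list(giants), spec,
                                       direction = blk$direction %||% "greater")
      out <- pth(blk$out %||% "result.json")
      jsonlite::write_json(list(
        statistic = res$statistic, direction = res$direction,
        observed = res$observed, p_value = res$p_value,
        floored = res$floored, n_random = res$n_random,
        null_sample = res$null_sample), out, auto_unbox = TRUE, digits = NA)
      c(result = out)
    },
    sizestats = {
      tabs <- lapply(unlist(blk$tables), read_cell_table)
      samples <- lapply(tabs, function(t)
        t$area_um2[is.na(t$cell_type) | t$cell_type != "stoma"])
      names(samples) <- basename(unlist(blk$tables))
      if (isTRUE(blk$normalize)) samples <- normalize_by_mean(samples)
      n <- length(samples)
      D <- matrix(0, n, n, dimnames = list(names(samples), names(samples)))
      for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
        D[i, j] <- D[j, i] <- wasserstein_1d(samples[[i]], samples[[j]])
      df <- pth(blk$out_dist %||% "dist.csv")
      write.csv(D, df)
      emb <- pcoa_embed(D)
      cf <- pth(blk$out_coords %||% "coords.csv")
      write.csv(data.frame(label = rownames(D), x = emb$coords[, 1],
                           y = emb$coords[, 2]), cf, row.names = FALSE)
      c(dist = df, coords = cf)
    },
    stop("config error: unknown stage '", blk$stage, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches `giantcell <subcommand> --key value ...`. Subcommands map to
#' single pipeline stages (`synth`, `classify`, `randomize`, `stats`,
#' `simulate`, `sizestats`) or to `pipeline --config cfg.yaml`. Used by the
#' wrapper script in `inst/exec/`.
#'
#' @param args character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
giantcell_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: giantcell <", paste(c(.pipeline_stages, "pipeline"), collapse = "|"),
            "> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  kv <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    vals <- character(0)
    while (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      vals <- c(vals, args[i + 1L]); i <- i + 1L
    }
    suppressWarnings({
      num <- as.numeric(vals)
      kv[[key]] <- if (!anyNA(num)) num else vals
    })
    if (length(vals) > 1L) kv[[key]] <- as.list(kv[[key]])
    i <- i + 1L
  }
  if (cmd == "pipeline") {
    run_pipeline(kv$config)
    return(invisible(0L))
  }
  if (!cmd %in% .pipeline_stages) stop("unknown subcommand: ", cmd)
  seed <- kv$seed %||% 1
  outdir <- kv$outdir %||% "."
  kv$seed <- NULL; kv$outdir <- NULL
  blk <- c(list(stage = cmd), kv)
  files <- run_stage(blk, as.integer(seed), outdir)
  message("wrote: ", paste(unlist(files), collapse = ", "))
  invisible(0L)
}
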