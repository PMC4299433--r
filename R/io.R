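# Configuration loading (JSON) and result writers.  A config fully
# describes a simulation: populations, projections, stimuli and runtime;
# simulation is a pure function of (config, seed), and every output
# directory carries a manifest with the config and its hash so runs are
# self-describing and reproducible.

rule_params_from_list <- function(name, lst) {
  ctor <- switch(name, stdp_trace = stdp_params, bcm = bcm_params,
                 vg_stdp = vg_params, NULL)
  if (is.null(ctor)) stop("unknown rule name: ", name)
  do.call(ctor, lst %||% list())
}

validate_config_obj <- function(cfg) {
  errs <- character(0)
  req <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  req(is.list(cfg$populations) && length(cfg$populations) > 0,
      "config needs a non-empty 'populations' list")
  pn <- character(0)
  for (p in cfg$populations %||% list()) {
    if (is.null(p$name) || is.null(p$n) || is.null(p$model)) {
      req(FALSE, "every population needs 'name', 'n' and 'model'")
      next
    }
    pn <- c(pn, p$name)
    req(p$model %in% c("lif", "source"),
        sprintf("population '%s': unknown model '%s'", p$name, p$model))
    if (identical(p$model, "source"))
      req(!is.null(p$stimulus$type),
          sprintf("source population '%s' needs a stimulus type", p$name))
    if (identical(p$model, "source") &&
        identical(p$stimulus$type, "poisson"))
      req((p$stimulus$rate %||% -1) >= 0,
          sprintf("population '%s': poisson rate must be >= 0", p$name))
  }
  req(!anyDuplicated(pn), "duplicate population names")
  for (pr in cfg$projections %||% list()) {
    nm <- paste0(pr$source %||% "?", "->", pr$target %||% "?")
    for (side in c("source", "target"))
      if (!(pr[[side]] %||% "") %in% pn)
        req(FALSE, sprintf("projection %s references unknown population '%s'",
                           nm, pr[[side]] %||% ""))
    ct <- pr$connectivity$type %||% "all_to_all"
    req(ct %in% c("one_to_one", "all_to_all", "bernoulli"),
        sprintf("projection %s: unknown connectivity '%s'", nm, ct))
    if (identical(ct, "bernoulli")) {
      p <- pr$connectivity$p %||% -1
      req(p >= 0 && p <= 1,
          sprintf("projection %s: bernoulli p must be in [0, 1]", nm))
    }
    if (isTRUE(pr$plastic))
      req((pr$rule$name %||% "") %in% c("stdp_trace", "bcm", "vg_stdp"),
          sprintf("projection %s: plastic but rule name missing/unknown",
                  nm))
  }
  rt <- cfg$runtime %||% list()
  req((rt$duration_ms %||% 0) >= 0, "runtime.duration_ms must be >= 0")
  lm <- cfg$plasticity$ledger_mode %||% "batched"
  req(lm %in% c("batched", "ded"),
      "plasticity.ledger_mode must be 'batched' or 'ded'")
  errs
}

#' Load and validate a simulation configuration
#'
#' Reads a JSON configuration describing populations, projections, stimuli
#' and runtime options.  All validation errors are collected and reported
#' together.
#'
#' @param path path to a JSON config file
#' @return a `sim_config` object
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  errs <- validate_config_obj(cfg)
  if (length(errs))
    stop("invalid configuration:\n", paste("-", errs, collapse = "\n"))
  structure(cfg, class = "sim_config")
}

#' Validate a configuration file without building it
#'
#' @param path path to a JSON config file
#' @return character vector of validation errors (empty if valid)
#' @export
validate_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_config_obj(cfg)
}

#' Build a network from a loaded configuration
#'
#' @param cfg a `sim_config` from [load_config()]
#' @param seed overrides `runtime.seed` when given
#' @return a [network()] object
#' @export
config_network <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$runtime$seed %||% 1
  pops <- lapply(cfg$populations, function(p) {
    st <- p$stimulus
    if (!is.null(st) && identical(st$type, "schedule"))
      st$times <- lapply(st$times, unlist)
    if (!is.null(st) && identical(st$type, "rate_schedule")) {
      st$onsets <- unlist(st$onsets)
      st$rates <- do.call(rbind, lapply(st$rates, unlist))
    }
    population(p$name, p$n, p$model,
               params = do.call(lif_params, p$params %||% list()),
               stimulus = st)
  })
  projs <- lapply(cfg$projections %||% list(), function(pr) {
    rule <- NULL
    if (isTRUE(pr$plastic))
      rule <- list(name = pr$rule$name,
                   params = rule_params_from_list(pr$rule$name,
                                                  pr$rule$params))
    projection(pr$source, pr$target,
               connectivity = pr$connectivity %||% list(type = "all_to_all"),
               weight = pr$weight %||% 1, delay = pr$delay %||% 1,
               receptor = pr$receptor %||% "exc",
               plastic = isTRUE(pr$plastic), rule = rule,
               name = pr$name %||% NULL)
  })
  network(pops, projs, seed = seed,
          window_ms = cfg_plast(cfg, "window_ms", 128),
          bin_ms = cfg_plast(cfg, "bin_ms", 2))
}

#' Run a simulation described by a configuration
#'
#' @param cfg a `sim_config` from [load_config()]
#' @param seed overrides `runtime.seed` when given
#' @return a `recording_set` from [run_network()]
#' @export
simulate_config <- function(cfg, seed = NULL) {
  seed <- seed %||% cfg$runtime$seed %||% 1
  net <- config_network(cfg, seed)
  run_network(net, cfg$runtime$duration_ms %||% 0, seed = seed,
              record_v = unlist(cfg$runtime$record_v) %||% integer(0),
              snapshots = cfg$runtime$snapshots %||% "boundaries")
}

cfg_plast <- function(cfg, key, default) {
  cfg$plasticity[[key]] %||% cfg$runtime[[key]] %||% default
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(cfg),
                                           auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write simulation or experiment outputs to a directory
#'
#' Writes the spike raster (`spikes.csv`, header `time_ms,neuron_id`),
#' membrane traces when recorded (`membrane.csv`, header
#' `time_ms,neuron_id,v_mV`), one weight-matrix file per plasticity
#' boundary snapshot (`weights_<proj>_<t>.txt`, tab-delimited pre x post
#' array), per-row write-back ledgers (`ledger_<proj>.csv`), a
#' `metrics.json` (experiment results) and a `run_manifest.json` with the
#' seed, package version and config hash.  Re-running with identical
#' inputs reproduces byte-identical files.
#'
#' @param result a `recording_set` or an `experiment_result`
#' @param outdir output directory (created if needed)
#' @param config optional configuration to embed in the manifest
#' @return invisibly, the vector of files written
#' @export
write_outputs <- function(result, outdir, config = NULL) {
  rec <- if (inherits(result, "experiment_result")) result$recordings
         else result
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", outdir)
  unlink(probe)
  files <- character(0)
  put <- function(f) { files <<- c(files, f); f }

  f <- put(file.path(outdir, "spikes.csv"))
  utils::write.csv(rec$spikes, f, row.names = FALSE, quote = FALSE)

  if (!is.null(rec$v)) {
    f <- put(file.path(outdir, "membrane.csv"))
    long <- data.frame(
      time_ms = rep(seq_len(nrow(rec$v)) - 1L, ncol(rec$v)),
      neuron_id = rep(rec$v_ids, each = nrow(rec$v)),
      v_mV = as.vector(rec$v))
    utils::write.csv(long, f, row.names = FALSE, quote = FALSE)
  }

  # weight snapshots: one dense pre x post matrix per boundary
  pmap <- list()
  for (pr in rec$projections)
    if (isTRUE(pr$plastic))
      pmap[[pr$name]] <- pr
  for (sn in rec$snapshots) {
    for (nm in names(sn$w)) {
      pr <- pmap[[nm]]
      m <- matrix(0, pr$n_pre, pr$n_post)
      m[cbind(pr$pre_local, pr$post_local)] <- sn$w[[nm]]
      f <- put(file.path(outdir, sprintf("weights_%s_%d.txt",
                                         safe_name(nm), sn$t)))
      utils::write.table(m, f, sep = "\t", row.names = FALSE,
                         col.names = FALSE)
    }
  }

  mode <- if (!is.null(config)) cfg_plast(config, "ledger_mode", "batched")
          else "batched"
  for (nm in names(rec$ledgers %||% list())) {
    f <- put(file.path(outdir, sprintf("ledger_%s.csv", safe_name(nm))))
    led <- rec$ledgers[[nm]]
    utils::write.csv(data.frame(
      row_id = seq_len(led$n_rows),
      writebacks = if (mode == "ded") led$ded else led$batched,
      alt_writebacks = if (mode == "ded") led$batched else led$ded),
      f, row.names = FALSE, quote = FALSE)
  }

  if (inherits(result, "experiment_result")) {
    f <- put(file.path(outdir, "metrics.json"))
    keep <- Filter(function(x) is.numeric(x) || is.logical(x) ||
                     is.character(x), result$metrics)
    jsonlite::write_json(keep, f, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }

  manifest <- list(
    package = "plastisim",
    version = as.character(utils::packageVersion("plastisim")),
    seed = rec$seed, duration_ms = rec$duration_ms,
    window_ms = rec$window_ms, bin_ms = rec$bin_ms,
    config = config %||%
      (if (inherits(result, "experiment_result")) result$config else NULL))
  manifest$config_hash <- if (!is.null(manifest$config))
    config_hash(manifest$config) else NA
  f <- put(file.path(outdir, "run_manifest.json"))
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(files)
}
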