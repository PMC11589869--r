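# Trace/manifest readers and writers and the end-to-end pipeline runner.

#' Write a cell recording to CSV
#'
#' Canonical plain-text trace container: header `time_s, cm_fF, ca_uM`, one
#' row per sample. Values are written with 9 significant digits (12 for the
#' time base, whose uniformity must survive the round trip).
#'
#' @param path output file path.
#' @param cm capacitance trace (fF).
#' @param ca calcium trace (uM) on the same time base.
#' @export
write_trace_csv <- function(path, cm, ca) {
  check_trace(cm, "fF"); check_trace(ca, "uM")
  if (length(cm$t) != length(ca$t) || max(abs(cm$t - ca$t)) > 1e-9)
    stop("cm and ca must share a time base", call. = FALSE)
  d <- data.frame(time_s = sprintf("%.12g", cm$t),
                  cm_fF = sprintf("%.9g", cm$v),
                  ca_uM = sprintf("%.9g", ca$v))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell recording from CSV
#'
#' Header-driven (column order free) parser for the CSV trace format of
#' [write_trace_csv()]. Validates numeric, finite values and uniform
#' sampling; the time base is regularized onto its exact uniform grid to
#' absorb decimal-formatting rounding.
#'
#' @param path CSV file with columns `time_s`, `cm_fF`, `ca_uM`.
#' @return List with elements `cm` (fF trace) and `ca` (uM trace).
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "cm_fF", "ca_uM")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in need) {
    x <- d[[col]]
    if (!is.numeric(x)) x <- suppressWarnings(as.numeric(x))
    bad <- which(!is.finite(x))
    if (length(bad))
      stop(sprintf("parse error in %s: non-numeric or non-finite value in column %s, row %d",
                   path, col, bad[1]), call. = FALSE)
    d[[col]] <- x
  }
  t <- d$time_s
  steps <- diff(t)
  dt <- stats::median(steps)
  if (dt <= 0 || max(abs(steps - dt)) > 1e-6 * dt)
    stop("parse error in ", path, ": time base not uniformly sampled",
         call. = FALSE)
  t <- t[1] + (seq_along(t) - 1) * dt   # exact uniform grid
  list(cm = new_trace(t, d$cm_fF, "fF"), ca = new_trace(t, d$ca_uM, "uM"))
}

MANIFEST_SCHEMA <- "1.0"

#' Write a simulated group to disk
#'
#' One CSV per cell plus a JSON manifest recording the group label,
#' protocol metadata, seed, per-cell files and the ground-truth generative
#' parameters (for recovery studies).
#'
#' @param dir output directory (created if needed).
#' @param cells a `"cell_population"` from [simulate_group()].
#' @param protocol_meta optional protocol description; defaults to the
#'   `meta` of the first cell's calcium trace.
#' @return Path of the manifest file, invisibly.
#' @export
write_group <- function(dir, cells, protocol_meta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(protocol_meta)) protocol_meta <- cells[[1]]$ca$meta
  entries <- lapply(cells, function(cl) {
    f <- paste0(cl$cell_id, ".csv")
    write_trace_csv(file.path(dir, f), cl$cm, cl$ca)
    list(id = cl$cell_id, file = f, params = unclass(cl$params))
  })
  manifest <- list(schema = MANIFEST_SCHEMA,
                   group = attr(cells, "group"),
                   seed = attr(cells, "seed"),
                   protocol = protocol_meta,
                   cells = entries)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Read a group manifest and its traces
#'
#' @param path manifest JSON path.
#' @return List with `group`, `seed`, `protocol` and `cells` (each
#'   `list(cell_id, cm, ca, params)`).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$schema) || m$schema != MANIFEST_SCHEMA)
    stop("unsupported manifest schema", call. = FALSE)
  base <- dirname(path)
  cells <- lapply(m$cells, function(e) {
    f <- file.path(base, e$file)
    if (!file.exists(f))
      stop("manifest refers to missing file: ", e$file, call. = FALSE)
    tr <- read_trace_csv(f)
    params <- if (!is.null(e$params)) do.call(cell_params, e$params) else NULL
    list(cell_id = e$id, cm = tr$cm, ca = tr$ca, params = params)
  })
  list(group = m$group, seed = m$seed, protocol = m$protocol, cells = cells)
}

# internal: flash analysis record for one cell
flash_record <- function(cell, t_flash, loading_window = NULL, ...) {
  fit <- fit_flash_response(cell$cm, t_flash, ...)
  rec <- as.list(stats::coef(fit))
  rec$rss <- fit$rss
  rec$converged <- fit$converged
  rec$n_points <- fit$n_points
  if (fit$converged && fit$identifiable) {
    rec <- c(rec, classify_components(fit))
  }
  if (!is.null(loading_window)) {
    ps <- measure_premature_secretion(cell$cm, cell$ca, loading_window)
    rec$premature_delta_cm <- ps$delta_cm
    rec$tonic_rate <- ps$tonic_rate
    rec$loading_mean_ca <- ps$mean_ca
  }
  rec
}

# internal: build a protocol trace from a config descriptor
protocol_from_config <- function(pc) {
  kind <- pc$kind
  if (is.null(kind)) stop("config error: protocol$kind missing", call. = FALSE)
  switch(kind,
    flash = make_flash_protocol(pc$ca_pre, pc$ca_post, pc$t_flash,
                                pc$duration, pc$dt),
    loading = make_flash_protocol(pc$ca, pc$ca, pc$duration / 2,
                                  pc$duration, pc$dt),
    ramp = make_ramp_protocol(pc$ca_start, pc$ca_end, pc$duration, pc$dt),
    stop("config error: unknown protocol kind ", kind, call. = FALSE))
}

# internal: stable hash of the configuration
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the simulate / analyze / compare pipeline from a configuration
#'
#' Configuration (YAML or JSON file, or an equivalent list) defines the
#' protocol, the simulated groups and the requested analyses; everything
#' downstream is seeded from the configuration, so reruns with an identical
#' configuration are byte-identical.
#'
#' Sections: `protocol` (kind `flash`/`ramp`/`loading` plus its
#' parameters), `groups` (list of `name`, `n_cells`, `cv`, `params`
#' overrides), `analyses` (subset of `"flash"`, `"ramp"`, `"compare"`),
#' `compare_field` (readout compared across groups, e.g. `"RRP"`), `seed`,
#' `ramp` (options passed to [analyze_ramp()]), `loading_window`.
#' Flash analyses are refused on ramp protocols and vice versa.
#'
#' @param config path to a YAML/JSON configuration or a list.
#' @param out_dir output directory (defaults to `config$out`).
#' @return Invisibly, the list of result file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_file <- NULL
  if (is.character(config)) {
    cfg_file <- config
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(out_dir)) out_dir <- config$out
  if (is.null(out_dir)) stop("config error: no output directory (out)",
                             call. = FALSE)
  if (is.null(config$groups) || !length(config$groups))
    stop("config error: groups missing", call. = FALSE)
  if (is.null(config$protocol))
    stop("config error: protocol missing", call. = FALSE)
  analyses <- config$analyses %||% "flash"
  kind <- config$protocol$kind
  if ("flash" %in% analyses && !kind %in% c("flash", "loading"))
    stop("flash analysis requested on a ", kind, " protocol: refused",
         call. = FALSE)
  if ("ramp" %in% analyses && kind != "ramp")
    stop("ramp analysis requested on a ", kind, " protocol: refused",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  protocol <- protocol_from_config(config$protocol)

  written <- character()
  jwrite <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, p)
    p
  }
  provenance <- list(package = "secretolyze",
                     version = as.character(utils::packageVersion("secretolyze")),
                     seed = seed, config_md5 = config_hash(config))

  groups <- list()
  for (i in seq_along(config$groups)) {
    gc <- config$groups[[i]]
    means <- if (!is.null(gc$params)) do.call(cell_params, as.list(gc$params))
             else cell_params()
    spec <- group_spec(gc$name, gc$n_cells, means = means,
                       cv = gc$cv %||% 0,
                       seed = child_seed(seed, i, stream = 1L))
    cells <- simulate_group(spec, protocol)
    write_group(file.path(out_dir, gc$name), cells)
    groups[[gc$name]] <- cells
  }

  flash_results <- NULL
  if ("flash" %in% analyses) {
    lw <- config$loading_window
    flash_results <- lapply(groups, function(cells)
      lapply(cells, function(cl) {
        rec <- flash_record(cl, t_flash = protocol$meta$t_flash,
                            loading_window = unlist(lw))
        c(list(cell_id = cl$cell_id), rec)
      }))
    jwrite(list(provenance = provenance, groups = flash_results),
           "flash_results.json")
  }

  if ("ramp" %in% analyses) {
    ro <- config$ramp %||% list()
    ramp_results <- lapply(names(groups), function(gn) {
      ra <- analyze_ramp(groups[[gn]],
                         ca_max = ro$ca_max[[gn]] %||% NULL,
                         poly_order = ro$poly_order %||% 12,
                         n_boot = ro$n_boot %||% 200,
                         seed = child_seed(seed, 7L, stream = 2L))
      list(group = gn, eb_mean = mean(ra$eb_sizes), ca_max = ra$ca_max,
           hill = as.list(stats::coef(ra$hill)),
           p50 = ra$depletion$p50, p50_se = ra$depletion$p50_se)
    })
    jwrite(list(provenance = provenance, groups = ramp_results),
           "ramp_results.json")
  }

  if ("compare" %in% analyses) {
    field <- config$compare_field %||% "RRP"
    if (is.null(flash_results))
      stop("compare requested without a flash analysis", call. = FALSE)
    samples <- lapply(flash_results, function(g)
      vapply(g, function(r) as.numeric(r[[field]] %||% NA_real_), 0))
    samples <- lapply(samples, function(x) x[is.finite(x)])
    cmp <- compare_groups(samples)
    jwrite(list(provenance = provenance, field = field,
                groups = cmp$groups, branch = cmp$branch,
                omnibus = cmp$omnibus, pairwise = cmp$pairwise),
           "comparison.json")
  }

  jwrite(provenance, "run_log.json")
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
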