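.SCHEMA_VERSION <- "1.0"

.config_defaults <- function() {
  list(modules = 0:8, anchor_target = "B",
       partner_targets = c("A", "B", "C", "D"),
       dose = 1, partner_dose = NULL, stimulus = "S0",
       horizon = 100, h = 0.01, crosstalk_scale = 1,
       scale_grid = 10^seq(0, 1, length.out = 8L),
       tol = 0.05, inhibition = "deactivation")
}

#' Load a screen configuration from JSON or YAML
#'
#' Reads a configuration document (format chosen by file extension), fills
#' in defaults for absent keys (horizon 100, h 0.01, dose 1, tol 0.05,
#' stimulus S0, all modules) and validates the result. Unknown keys are
#' rejected so that typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file. An empty document
#'   yields the all-defaults configuration.
#' @return A `screen_config`.
#' @export
load_screen_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported config extension '.", ext, "' (use json or yaml)")
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config document must be a mapping of keys")
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), c(names(defaults), "schema_version"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  raw$schema_version <- NULL
  merged <- utils::modifyList(defaults, raw)
  if (is.null(merged$partner_dose)) merged$partner_dose <- merged$dose
  cfg <- tryCatch(do.call(screen_config, merged), error = function(e)
    stop("invalid config in ", path, ": ", conditionMessage(e)))
  cfg
}

.manifest <- function(result, config_json) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_json, tmp)
  m <- list(
    schema_version = .SCHEMA_VERSION,
    package = "crosstalksim",
    package_version = as.character(utils::packageVersion("crosstalksim")),
    kind = attr(result, "kind"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(result),
    config = jsonlite::fromJSON(config_json),
    config_hash = unname(tools::md5sum(tmp))
  )
  # scan summaries ride along so the round-trip is lossless
  if (!is.null(attr(result, "switching"))) {
    m$switching <- attr(result, "switching")
  }
  if (!is.null(attr(result, "majority_resistant"))) {
    m$majority_resistant <- attr(result, "majority_resistant")
  }
  m
}

.config_as_json <- function(cfg) {
  jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
}

#' Write a screen result (tables plus manifest) to a directory
#'
#' Writes the long-form record table as `result.csv` and/or `result.json`
#' together with a `manifest.json` recording the schema version, package
#' version, screen kind, timestamps, the full configuration echo and its
#' hash. The JSON table round-trips the numeric values at full precision.
#'
#' @param result A `screen_result`.
#' @param dir Output directory (created if absent).
#' @param format Subset of `c("csv", "json")`.
#' @return Invisibly, the paths written.
#' @export
write_screen_result <- function(result, dir, format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  cfg_json <- .config_as_json(attr(result, "config"))
  paths <- character(0)
  if ("csv" %in% format) {
    p <- file.path(dir, "result.csv")
    utils::write.csv(as.data.frame(result), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% format) {
    p <- file.path(dir, "result.json")
    jsonlite::write_json(as.data.frame(result), p, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(.manifest(result, cfg_json), mp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}

#' Read back a screen result written by [write_screen_result()]
#'
#' Prefers the JSON table (lossless) and falls back to the CSV. The
#' manifest supplies the screen kind and configuration.
#'
#' @param dir Directory containing `manifest.json` and a result table.
#' @return A `screen_result`.
#' @export
read_screen_result <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mp)
  jp <- file.path(dir, "result.json")
  cp <- file.path(dir, "result.csv")
  df <- if (file.exists(jp)) {
    jsonlite::fromJSON(jp)
  } else if (file.exists(cp)) {
    utils::read.csv(cp, stringsAsFactors = FALSE)
  } else {
    stop("no result table (result.json / result.csv) in ", dir)
  }
  cfg <- manifest$config
  cfg$partner_dose <- cfg$partner_dose %||% cfg$dose
  cfg <- do.call(screen_config, cfg)
  df$module_id <- as.integer(df$module_id)
  out <- .as_screen_result(df, manifest$kind, cfg)
  if (!is.null(manifest$switching)) {
    attr(out, "switching") <- as.data.frame(manifest$switching)
  }
  if (!is.null(manifest$majority_resistant)) {
    attr(out, "majority_resistant") <- as.integer(manifest$majority_resistant)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialise the canned scenario fixtures
#'
#' Writes the nine module topologies, the standard parameter set, the seven
#' stimulus profiles and the standard single-drug and combination regimens
#' as JSON files (one scenario per file, each stamped with the schema
#' version). These are the inputs used by the examples and the test suite.
#'
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  wj <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(c(list(schema_version = .SCHEMA_VERSION), x), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  paths <- character(0)
  for (m in 0:8) {
    top <- build_module(m)
    paths <- c(paths, wj(list(module_id = top$module_id,
                              V = top$V, K = top$K,
                              crosstalk_edges = top$crosstalk_edges,
                              crosstalk_scale = top$crosstalk_scale),
                         sprintf("module_%d.json", m)))
  }
  paths <- c(paths, wj(unclass(default_parameters()), "parameters.json"))
  lib <- stimulus_library()
  for (nm in names(lib)) {
    paths <- c(paths, wj(list(name = nm, segments = lib[[nm]]$G1$segments),
                         sprintf("stimulus_%s.json", nm)))
  }
  regs <- list(untreated = drug_regimen(),
               single_B = drug_regimen("B"))
  for (px in c("A", "B", "C", "D")) {
    regs[[paste0("combo_B", px)]] <- drug_regimen(c("B", px))
  }
  for (nm in names(regs)) {
    paths <- c(paths, wj(list(label = regimen_label(regs[[nm]]),
                              entries = regs[[nm]]$entries),
                         sprintf("regimen_%s.json", nm)))
  }
  invisible(paths)
}

#' Read a module topology fixture back into a `module_topology`
#'
#' @param path A `module_*.json` file written by [generate_fixtures()].
#' @return A `module_topology`.
#' @export
read_topology <- function(path) {
  x <- jsonlite::fromJSON(path)
  ce <- x$crosstalk_edges
  if (is.null(ce) || length(ce) == 0L) {
    ce <- cbind(from = integer(0), to = integer(0))
  } else {
    ce <- matrix(as.integer(ce), ncol = 2L,
                 dimnames = list(NULL, c("from", "to")))
  }
  module_topology(V = matrix(as.numeric(x$V), 5L, 5L),
                  K = matrix(as.numeric(x$K), 5L, 5L),
                  crosstalk_edges = ce,
                  module_id = x$module_id,
                  crosstalk_scale = x$crosstalk_scale)
}
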