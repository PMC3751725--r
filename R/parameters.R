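# Typed parameter model: validation, dot-path access, config file I/O and
# scenario application.

#' Validate a parameter set
#'
#' Checks the structural and physical invariants of a `cvloop_params`
#' object (positive dimensions and volumes, bounded fractions, existing
#' topology references).  Errors name the offending field.
#'
#' @param params A `cvloop_params` object.
#' @return The validated object, invisibly.
#' @export
cv_validate <- function(params) {
  g <- params$global
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("invalid configuration: ", field, " ", msg,
                            call. = FALSE)
  }
  chk(g$blood_volume > 0, "global.blood_volume", "must be positive")
  chk(g$dt > 0, "global.dt", "must be positive")
  chk(g$hb > 0, "global.hb", "must be positive")
  chk(g$heart_rate >= 0, "global.heart_rate", "must be non-negative")
  chk(g$damping_lambda >= 0 && g$damping_lambda <= 1,
      "global.damping_lambda", "must be in [0, 1]")
  chk(g$pulm_shunt_fraction >= 0 && g$pulm_shunt_fraction <= 1,
      "global.pulm_shunt_fraction", "must be in [0, 1]")

  for (cn in names(params$chambers)) {
    ch <- params$chambers[[cn]]
    f <- function(x) paste0("chambers.", cn, ".", x)
    chk(ch$e_min > 0, f("e_min"), "must be positive")
    chk(ch$e_max >= ch$e_min, f("e_max"), "must be >= e_min")
    chk(ch$alpha1 > 0 && ch$alpha2 > 0, f("alpha1/alpha2"),
        "must be positive")
    chk(ch$onset >= 0, f("onset"), "must be non-negative")
    chk(ch$phi_dia > 0, f("phi_dia"), "must be positive")
    chk(ch$init_volume > 0, f("init_volume"), "must be positive")
  }
  for (vn in names(params$valves)) {
    va <- params$valves[[vn]]
    f <- function(x) paste0("valves.", vn, ".", x)
    chk(va$a_min >= 0, f("a_min"), "must be non-negative")
    chk(va$a_max >= va$a_min, f("a_max"), "must be >= a_min")
    chk(va$k_open > 0 && va$k_close > 0, f("k_open/k_close"),
        "must be positive")
  }
  groups <- c("extrathoracic", "intrathoracic", "pericardial")
  for (sn in names(params$segments)) {
    s <- params$segments[[sn]]
    f <- function(x) paste0("segments.", sn, ".", x)
    chk(s$length > 0, f("length"), "must be positive")
    chk(s$radius0 > 0, f("radius0"), "must be positive")
    chk(s$thickness > 0, f("thickness"), "must be positive")
    chk(s$count > 0, f("count"), "must be positive")
    chk(s$p0 > 0, f("p0"), "must be positive")
    chk(s$external_group %in% groups, f("external_group"),
        paste("must be one of", paste(groups, collapse = ", ")))
    chk(is.na(s$compress_chamber) ||
          s$compress_chamber %in% chamber_names,
        f("compress_chamber"), "must be a chamber name or NA")
    chk(s$init_volume > 0, f("init_volume"), "must be positive")
  }
  chk(params$septum$esv0 > 0, "septum.esv0", "must be positive")
  chk(params$septum$esa > 0, "septum.esa", "must be positive")
  chk(params$pericardium$phi > 0, "pericardium.phi", "must be positive")

  comps <- compartment_names(params)
  topo <- params$topology
  bad <- setdiff(unique(c(topo$from, topo$to)), comps)
  chk(length(bad) == 0, "topology",
      paste("references unknown compartments:", paste(bad, collapse = ", ")))
  for (s in c("asd", "vsd", "pda"))
    chk(params$shunts[[s]]$area >= 0, paste0("shunts.", s, ".area"),
        "must be non-negative")
  invisible(params)
}

# ---- dot-path access ---------------------------------------------------

#' Enumerate, read and patch parameters by dot-separated path
#'
#' Parameters are addressed by paths such as `"chambers.lv.e_max"`,
#' `"segments.sys_arteriolae.radius0"` or
#' `"global.intrathoracic_pressure"`.  `cv_paths()` lists every patchable
#' leaf; `cv_get()`/`cv_set()` read and (non-destructively) write one.
#'
#' @param params A `cvloop_params` object.
#' @param path Dot-separated parameter path.
#' @param value Replacement value (scalar).
#' @return `cv_set()` returns a modified copy; `params` is unchanged.
#' @export
cv_paths <- function(params) {
  leaves <- function(x, prefix) {
    out <- character()
    for (nm in names(x)) {
      el <- x[[nm]]
      p <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(el)) out <- c(out, leaves(el, p))
      else if ((is.numeric(el) || is.logical(el) || is.character(el)) &&
               length(el) == 1)
        out <- c(out, p)
    }
    out
  }
  skip <- c("topology")
  leaves(params[setdiff(names(params), skip)], "")
}

#' @rdname cv_paths
#' @export
cv_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- params
  for (p in parts) {
    if (!is.list(x) || is.null(x[[p]]))
      stop("unknown parameter path '", path, "'; valid paths include:\n  ",
           paste(utils::head(cv_paths(params), 12), collapse = "\n  "),
           "\n  ... (see cv_paths())", call. = FALSE)
    x <- x[[p]]
  }
  x
}

#' @rdname cv_paths
#' @export
cv_set <- function(params, path, value) {
  cv_get(params, path)  # existence check with informative error
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  params[[parts]] <- value
  params
}

# ---- config file I/O ---------------------------------------------------

#' Read and write parameter configurations
#'
#' Parameter sets are stored as JSON.  `load_config()` validates on read
#' and reports schema violations by field name; `write_config()` writes
#' with full numeric precision so that
#' `load_config(write_config(p)) == p` field for field.
#'
#' @param path File path.
#' @param params A `cvloop_params` object.
#' @return `load_config()`: a validated `cvloop_params`;
#'   `write_config()`: `path`, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  raw$topology <- as.data.frame(raw$topology)
  # scalar NA fields round-trip as NULL in JSON
  for (sn in names(raw$segments)) {
    s <- raw$segments[[sn]]
    for (f in c("compress_chamber", "lambda"))
      if (is.null(s[[f]])) raw$segments[[sn]][[f]] <- NA
  }
  class(raw) <- "cvloop_params"
  cv_validate(raw)
  raw
}

#' @rdname load_config
#' @export
write_config <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       always_decimal = FALSE)
  invisible(path)
}

# ---- scenarios ---------------------------------------------------------

#' Available scenario presets
#'
#' Scenario definitions shipped with the package: parameter patches (and
#' optionally timed events) applied on top of the baseline preset.
#'
#' @return Character vector of scenario names.
#' @export
cv_scenarios <- function() {
  dir <- system.file("extdata", "presets", package = "cvloop")
  sort(sub("\\.json$", "", list.files(dir, pattern = "\\.json$")))
}

#' Load a scenario definition
#'
#' @param name Scenario name (see [cv_scenarios()]) or a path to a JSON
#'   scenario file.
#' @return A `cvloop_scenario` list with `name`, `patches` (data frame
#'   `path`/`value`) and `events` (data frame
#'   `t_start`/`t_end`/`path`/`value`).
#' @export
cv_scenario <- function(name) {
  path <- if (file.exists(name)) name
          else system.file("extdata", "presets", paste0(name, ".json"),
                           package = "cvloop")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown scenario '", name, "'; valid scenarios: ",
         paste(cv_scenarios(), collapse = ", "), call. = FALSE)
  sc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  sc$patches <- if (length(sc$patches)) as.data.frame(sc$patches)
                else data.frame(path = character(), value = numeric())
  sc$events <- if (length(sc$events)) as.data.frame(sc$events)
               else data.frame(t_start = numeric(), t_end = numeric(),
                               path = character(), value = numeric())
  class(sc) <- "cvloop_scenario"
  sc
}

#' Apply a scenario to a parameter set
#'
#' Applies the scenario's absolute parameter patches (idempotent) and
#' attaches its timed events for the solver.  The base parameter set is
#' not modified.  Every patched path must exist in the base configuration;
#' unknown paths raise an error listing valid paths.
#'
#' @param base A `cvloop_params` object.
#' @param scenario A `cvloop_scenario` (from [cv_scenario()]) or a
#'   scenario name.
#' @return A new `cvloop_params` with an `"events"` attribute holding the
#'   timed events (expanded to set/restore pairs).
#' @export
apply_scenario <- function(base, scenario) {
  if (is.character(scenario)) scenario <- cv_scenario(scenario)
  params <- base
  if (nrow(scenario$patches))
    for (i in seq_len(nrow(scenario$patches)))
      params <- cv_set(params, scenario$patches$path[i],
                       scenario$patches$value[i])
  ev <- data.frame(t = numeric(), path = character(), value = numeric())
  if (nrow(scenario$events)) {
    se <- scenario$events
    if (any(se$t_start >= se$t_end))
      stop("invalid scenario events: t_start must be < t_end")
    for (i in seq_len(nrow(se))) {
      base_val <- cv_get(params, se$path[i])  # also validates the path
      ev <- rbind(ev,
                  data.frame(t = se$t_start[i], path = se$path[i],
                             value = se$value[i]),
                  data.frame(t = se$t_end[i], path = se$path[i],
                             value = base_val))
    }
  }
  cv_validate(params)
  attr(params, "events") <- ev
  params
}
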