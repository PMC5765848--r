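#' Scenario configurations
#'
#' A scenario bundles everything needed to reproduce a computation:
#' geometry, window layout, source, simulation parameters and the task to
#' run. Scenarios are stored as JSON with a versioned schema;
#' `read_scenario()` validates strictly (unknown keys are rejected, every
#' geometric invariant is enforced at load time) and returns a
#' `gs_scenario` object whose `windows` element feeds directly into the
#' computational functions.
#'
#' The JSON layout is:
#' \preformatted{
#' {
#'   "schema": "gradsense-scenario/1",
#'   "task": "flux" | "simulate" | "recover" | "sensitivity-map",
#'   "geometry": {"type": "half_plane", "side": 1} |
#'               {"type": "exterior_disk", "R": 1} |
#'               {"type": "disk_in_strip", "R": 1, "a": 2},
#'   "windows": {"z": [...]} or {"theta": [...]},   // centres
#'   "eps": 0.1,
#'   "source": {"x": -2, "y": 8, "D": 1},
#'   "sim": {"n": 1e5, "seed": 1, "re": null, "ro": null, "dt": null,
#'           "max_reinject": 10000},                 // optional
#'   "observed": [...]                               // recover task only
#' }
#' }
#'
#' @param path Path to a scenario JSON file.
#' @param scenario A `gs_scenario` object.
#' @return `read_scenario()` returns a `gs_scenario` list with elements
#'   `task`, `geometry`, `windows` (a [window set][window_set]), `source`,
#'   `D`, `sim` and optionally `observed`. `write_scenario()` writes the
#'   JSON representation and returns the path invisibly.
#' @name scenario_io
NULL

.scenario_schema <- "gradsense-scenario/1"
.scenario_tasks <- c("flux", "simulate", "recover", "sensitivity-map")

#' @rdname scenario_io
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("scenario file '%s' does not exist.", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_scenario(raw)
}

validate_scenario <- function(raw) {
  known <- c("schema", "task", "geometry", "windows", "eps", "source", "sim",
             "observed")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    abort(sprintf("unknown scenario field(s): %s", paste(extra, collapse = ", ")))
  for (field in c("schema", "task", "geometry", "windows", "eps", "source")) {
    if (is.null(raw[[field]]))
      abort(sprintf("scenario is missing required field '%s'.", field))
  }
  if (!identical(raw$schema, .scenario_schema))
    abort(sprintf("unsupported schema '%s' (expected '%s').",
                  raw$schema, .scenario_schema))
  if (!raw$task %in% .scenario_tasks)
    abort(sprintf("unknown task '%s'; must be one of %s.", raw$task,
                  paste(.scenario_tasks, collapse = ", ")))

  g <- raw$geometry
  if (is.null(g$type)) abort("geometry block is missing its 'type' tag.")
  geometry <- switch(g$type,
    half_plane = {
      check_keys(g, c("type", "side"), "geometry")
      half_plane(side = g$side %||% 1)
    },
    exterior_disk = {
      check_keys(g, c("type", "R"), "geometry")
      exterior_disk(R = g$R %||% 1)
    },
    disk_in_strip = {
      check_keys(g, c("type", "R", "a"), "geometry")
      disk_in_strip(R = g$R %||% 1, a = g$a %||% 2)
    },
    abort(sprintf("unknown geometry type '%s'.", g$type)))

  w <- raw$windows
  eps <- raw$eps
  windows <- if (!is.null(w$z)) {
    check_keys(w, "z", "windows")
    if (geometry$type != "half_plane")
      abort("boundary coordinates 'z' require the half-plane geometry.")
    windows_on_line(unlist(w$z), eps = eps, geometry = geometry)
  } else if (!is.null(w$theta)) {
    check_keys(w, "theta", "windows")
    if (geometry$type == "half_plane")
      abort("window angles 'theta' require a disk geometry.")
    windows_on_disk(unlist(w$theta), eps = eps, geometry = geometry)
  } else {
    abort("windows block must give centres as 'z' (half-plane) or 'theta' (disk).")
  }

  s <- raw$source
  check_keys(s, c("x", "y", "D"), "source")
  source <- c(s$x, s$y)
  assert_source(windows, source)
  D <- s$D %||% 1
  if (D <= 0) abort("diffusivity D must be positive.")

  sim <- raw$sim %||% list()
  check_keys(sim, c("n", "seed", "re", "ro", "dt", "max_reinject"), "sim")
  sim <- list(n = sim$n %||% 1e5, seed = sim$seed %||% 1,
              re = sim$re, ro = sim$ro, dt = sim$dt,
              max_reinject = sim$max_reinject %||% 1e4)

  out <- list(task = raw$task, geometry = geometry, windows = windows,
              source = source, D = D, sim = sim)
  if (!is.null(raw$observed)) {
    out$observed <- check_observed(unlist(raw$observed), nrow(windows))
  } else if (raw$task == "recover") {
    abort("the 'recover' task requires an 'observed' probability vector.")
  }
  structure(out, class = "gs_scenario")
}

check_keys <- function(block, allowed, name) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0)
    abort(sprintf("unknown key(s) in '%s' block: %s", name,
                  paste(extra, collapse = ", ")))
  invisible(block)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_to_list <- function(scenario) {
  g <- scenario$geometry
  gl <- switch(g$type,
    half_plane = list(type = "half_plane", side = g$side),
    exterior_disk = list(type = "exterior_disk", R = g$R),
    disk_in_strip = list(type = "disk_in_strip", R = g$R, a = g$a))
  wl <- if (g$type == "half_plane") {
    list(z = scenario$windows$y)
  } else {
    list(theta = atan2(scenario$windows$y, scenario$windows$x))
  }
  out <- list(schema = .scenario_schema, task = scenario$task, geometry = gl,
              windows = wl, eps = ws_eps(scenario$windows),
              source = list(x = scenario$source[1], y = scenario$source[2],
                            D = scenario$D),
              sim = scenario$sim)
  if (!is.null(scenario$observed)) out$observed <- scenario$observed
  out
}

#' @rdname scenario_io
#' @param path Output file path.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "gs_scenario"))
  jsonlite::write_json(scenario_to_list(scenario), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.gs_scenario <- function(x, ...) {
  cat(sprintf("<gs_scenario> task '%s', %d windows, source (%.4g, %.4g)\n",
              x$task, nrow(x$windows), x$source[1], x$source[2]))
  print(x$geometry)
  invisible(x)
}

#' Built-in reference scenarios
#'
#' Code-generated scenario fixtures for the reference configurations used
#' throughout the package's validation suite: nothing is downloaded or
#' checked in, every scenario is rebuilt from these few parameters.
#'
#' * `"fig3_halfplane"`: two windows a distance 1 apart (`z = +/- 0.5`,
#'   `eps = 0.1`) on the half-plane boundary; the scenario carries a
#'   `sweep` tibble over source distances `L = 2, 5, 10` and a grid of 9
#'   source angles.
#' * `"fig4_three_windows"`: three windows at `z = -1, 0, 1`, source at
#'   `(-2, 8)` (domain `x < 0`).
#' * `"fig4_five_windows"`: five windows with nearest-neighbour spacing 1,
#'   same source.
#' * `"fig6_disk_stability"`: two windows on a unit disk; `sweep` over
#'   inner radii `re = 1.3, 2, 3` and two outer radii.
#' * `"strip_demo"`: the unit disk inside a strip of half-width 2 with a
#'   symmetric two-window layout.
#'
#' @param name Scenario name.
#' @return A `gs_scenario` object; sweep scenarios carry an extra `sweep`
#'   tibble.
#' @examples
#' scenario_fixture("fig4_three_windows")
#' @export
scenario_fixture <- function(name = c("fig3_halfplane", "fig4_three_windows",
                                      "fig4_five_windows",
                                      "fig6_disk_stability", "strip_demo")) {
  name <- match.arg(name)
  sc <- switch(name,
    fig3_halfplane = {
      theta <- seq(-pi / 2, pi / 2, length.out = 9)
      sweep <- tidyr::expand_grid(L = c(2, 5, 10), theta = theta)
      structure(list(
        task = "simulate", geometry = half_plane(),
        windows = windows_on_line(c(0.5, -0.5), eps = 0.1),
        source = c(2, 0), D = 1,
        sim = list(n = 1e5, seed = 1, re = NULL, ro = NULL, dt = NULL,
                   max_reinject = 1e4),
        sweep = sweep), class = "gs_scenario")
    },
    fig4_three_windows = {
      w <- windows_on_line(c(-1, 0, 1), eps = 0.1, geometry = half_plane(-1))
      structure(list(
        task = "recover", geometry = half_plane(-1), windows = w,
        source = c(-2, 8), D = 1,
        sim = list(n = 1e5, seed = 1, re = NULL, ro = NULL, dt = NULL,
                   max_reinject = 1e4),
        observed = window_system(w, c(-2, 8))$p[1:2]), class = "gs_scenario")
    },
    fig4_five_windows = {
      w <- windows_on_line(-2:2, eps = 0.1, geometry = half_plane(-1))
      structure(list(
        task = "recover", geometry = half_plane(-1), windows = w,
        source = c(-2, 8), D = 1,
        sim = list(n = 1e5, seed = 1, re = NULL, ro = NULL, dt = NULL,
                   max_reinject = 1e4),
        observed = window_system(w, c(-2, 8))$p[1:4]), class = "gs_scenario")
    },
    fig6_disk_stability = {
      sweep <- tidyr::expand_grid(re = c(1.3, 2, 3), ro = c(4, 6))
      structure(list(
        task = "simulate", geometry = exterior_disk(R = 1),
        windows = windows_on_disk(c(0, 3 * pi / 4), eps = 0.1),
        source = c(4 * cos(pi / 6), 4 * sin(pi / 6)), D = 1,
        sim = list(n = 1e5, seed = 1, re = NULL, ro = NULL, dt = NULL,
                   max_reinject = 1e4),
        sweep = sweep), class = "gs_scenario")
    },
    strip_demo = structure(list(
      task = "simulate", geometry = disk_in_strip(R = 1, a = 2),
      windows = windows_on_disk(c(0, pi), eps = 0.1,
                                geometry = disk_in_strip(R = 1, a = 2)),
      source = c(6, 0.5), D = 1,
      sim = list(n = 1e5, seed = 1, re = 1.5, ro = 3, dt = NULL,
                 max_reinject = 1e4)), class = "gs_scenario"))
  sc
}

#' Write results with full provenance
#'
#' Serializes a splitting result or recovery result to JSON (with the
#' package version, seed and a hash of the generating configuration) and,
#' optionally, a flat CSV table. Re-serializing a loaded JSON result is
#' byte-identical.
#'
#' @param result A `gs_split`, `gs_recovery` or any tibble-like result.
#' @param path Output path without extension (``.json`` / ``.csv`` are
#'   appended), or with ``.json`` extension which is stripped first.
#' @param format `"json"`, `"csv"` or `"both"`.
#' @return Invisibly, the paths written.
#' @examples
#' w <- windows_on_line(c(0.5, -0.5), eps = 0.1)
#' res <- splitting_closed_form(w, source = c(1, 2))
#' paths <- write_results(res, file.path(tempdir(), "flux"), format = "both")
#' @export
write_results <- function(result, path, format = c("both", "json", "csv")) {
  format <- match.arg(format)
  stem <- sub("\\.(json|csv)$", "", path)
  paths <- character(0)

  payload <- result_payload(result)
  if (format %in% c("both", "json")) {
    jp <- paste0(stem, ".json")
    jsonlite::write_json(payload, jp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths <- c(paths, jp)
  }
  if (format %in% c("both", "csv")) {
    cp <- paste0(stem, ".csv")
    utils::write.csv(result_table(result), cp, row.names = FALSE)
    paths <- c(paths, cp)
  }
  invisible(paths)
}

result_table <- function(result) {
  if (inherits(result, "gs_recovery")) return(as.data.frame(glance(result)))
  as.data.frame(result)
}

result_payload <- function(result) {
  meta <- list(package = "gradsense",
               version = as.character(utils::packageVersion("gradsense")))
  if (inherits(result, "gs_split")) {
    cfg <- attr(result, "config")
    core <- list(
      kind = "splitting", provenance = attr(result, "provenance"),
      source = as.numeric(attr(result, "source")),
      eps = attr(result, "eps"),
      geometry = attr(result, "geometry")$type,
      windows = lapply(seq_len(nrow(result)), function(i)
        list(window = result$window[i], x = result$x[i], y = result$y[i],
             p = result$p[i], se = result$se[i])),
      config = cfg)
    if (!is.null(cfg)) {
      core$seed <- cfg$seed
      core$config_hash <- fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                   digits = NA))
    }
    c(meta, core)
  } else if (inherits(result, "gs_recovery")) {
    c(meta, list(kind = "recovery",
                 position = as.numeric(result$position),
                 residual = result$residual,
                 ambiguous = result$ambiguous,
                 observed = as.numeric(result$observed),
                 candidates = as.data.frame(result$candidates)))
  } else {
    c(meta, list(kind = "table", data = as.data.frame(result)))
  }
}

## 32-bit FNV-1a over the UTF-8 bytes of a string; small self-contained
## fingerprint for config provenance (16-bit split avoids double overflow)
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  m <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # multiply mod 2^32 in 16-bit halves to stay within double precision
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  lo <- as.integer(h %% 65536); hi <- as.integer((h - lo) / 65536)
  sprintf("%04x%04x", hi, lo)
}

#' Read back a results JSON
#'
#' @param path Path to a JSON file written by [write_results()].
#' @return The parsed payload list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
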