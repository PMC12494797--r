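# One-config orchestration of the full analysis workflow:
# Guinier -> Kratky -> p(r) -> invariants -> map check -> rigid-body fit.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = file.path(tempdir(), "saxsfit_run"),
    curve = NULL, model = NULL, bodies = NULL, map = NULL,
    stages = list(guinier = TRUE, kratky = TRUE, pr = TRUE,
                  invariants = TRUE, mapfit = FALSE, rbfit = FALSE),
    guinier = list(qmax_rg = 1.3),
    pr = list(n_r = 101, mode = "bayes"),
    invariants = list(porod_divisor = 1600, kc = 0.10),
    mapfit = list(n_levels = 25, max_beads = 20000),
    rb = list(n_runs = 10, n_steps = 3000, fit_oligomer = FALSE)
  )
}

# stable hash of the resolved configuration (for the run log); the output
# directory is excluded so re-runs into different directories hash alike
.config_hash <- function(config) {
  config$outdir <- NULL
  txt <- jsonlite::toJSON(
    purrr::map(config, function(x) if (is.function(x)) "function" else x),
    auto_unbox = TRUE, force = TRUE, digits = 12)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in order (Guinier, dimensionless Kratky,
#' p(r), Porod/correlation-volume invariants, density-map threshold fit,
#' rigid-body refinement), each consuming prior outputs, and writes a
#' machine-readable `summary.json` plus per-stage artefacts (reports,
#' fitted-curve `.dat` files, p(r) table, refined model PDB) into the
#' output directory.  A stage failure aborts with the stage name; partial
#' outputs are retained.
#'
#' @param config A named list, or path to a YAML file.  Recognised fields:
#'   `curve` (path or `saxs_curve`), `model` (path or
#'   `structure_model`), `bodies` (segment table for
#'   [decompose_bodies()]), `map` (path or `density_map`), `stages`
#'   (named logicals), per-stage parameter lists (`guinier`, `pr`,
#'   `invariants`, `mapfit`, `rb`), `seed`, `outdir`.
#' @return The summary list (class `saxs_pipeline`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(.pipeline_defaults(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  summary <- list(
    package_version = as.character(utils::packageVersion("saxsfit")),
    seed = cfg$seed)
  summary$config_hash <- .config_hash(cfg)
  results <- list()

  run_stage <- function(name, enabled, fn) {
    if (!isTRUE(enabled)) return(NULL)
    tryCatch(fn(), error = function(e) {
      jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                           auto_unbox = TRUE, digits = 12)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  curve <- NULL
  if (!is.null(cfg$curve)) {
    curve <- if (is.character(cfg$curve)) read_saxs(cfg$curve) else {
      as_saxs_curve(cfg$curve)
    }
  }
  model <- NULL
  if (!is.null(cfg$model)) {
    model <- if (is.character(cfg$model)) read_structure(cfg$model) else {
      cfg$model
    }
  }

  gui <- NULL
  if (!is.null(curve)) {
    gui <- run_stage("guinier", cfg$stages$guinier, function() {
      g <- guinier_fit(curve, qmax_rg = cfg$guinier$qmax_rg,
                       qmin = cfg$guinier$qmin)
      summary$guinier <<- as.list(glance(g))
      results$guinier <<- g
      g
    })
    run_stage("kratky", cfg$stages$kratky && !is.null(gui), function() {
      k <- kratky_transform(curve, gui)
      summary$kratky <<- list(plateau = kratky_plateau(k),
                              peak_x = k$x[which.max(k$y)],
                              peak_y = max(k$y))
      k
    })
    run_stage("pr", cfg$stages$pr, function() {
      pr <- pr_transform(curve, dmax = cfg$pr$dmax, n_r = cfg$pr$n_r,
                         mode = cfg$pr$mode, guinier = gui)
      summary$pr <<- as.list(glance(pr))
      results$pr <<- pr
      write_pr(pr, file.path(cfg$outdir, "pr.dat"))
      bt <- pr_back_transform(pr, curve$q)
      write_saxs(curve, file.path(cfg$outdir, "pr_fit.dat"), I_model = bt$I)
      pr
    })
    run_stage("invariants", cfg$stages$invariants && !is.null(gui), function() {
      inv <- saxs_invariants(curve, gui,
                             porod_divisor = cfg$invariants$porod_divisor,
                             kc = cfg$invariants$kc)
      summary$invariants <<- as.list(glance(inv))
      results$invariants <<- inv
      inv
    })
  }

  if (!is.null(cfg$map) && !is.null(curve)) {
    run_stage("mapfit", cfg$stages$mapfit, function() {
      map <- if (is.character(cfg$map)) read_density_map(cfg$map) else cfg$map
      sc <- threshold_scan(map, curve, n_levels = cfg$mapfit$n_levels,
                           max_beads = cfg$mapfit$max_beads)
      summary$mapfit <<- as.list(glance(sc))
      results$mapfit <<- sc
      write_pdb(sc$best_beads, file.path(cfg$outdir, "map_dummy_atoms.pdb"))
      sc
    })
  }

  if (!is.null(model) && !is.null(cfg$bodies) && !is.null(curve)) {
    run_stage("rbfit", cfg$stages$rbfit, function() {
      dec <- decompose_bodies(model, cfg$bodies)
      rcfg <- do.call(rb_config, c(cfg$rb, list(seed = cfg$seed)))
      rb <- rb_refine(dec, curve, rcfg)
      summary$rbfit <<- as.list(glance(rb))
      results$rbfit <<- rb
      write_pdb(rb$beads, file.path(cfg$outdir, "rb_best.pdb"))
      write_saxs(curve, file.path(cfg$outdir, "rb_fit.dat"),
                 I_model = rb$fit$data$I_model)
      rb
    })
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 12)
  write_report(results, file.path(cfg$outdir, "report.txt"))
  class(summary) <- "saxs_pipeline"
  invisible(summary)
}

#' @export
print.saxs_pipeline <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ")\n")
  for (nm in setdiff(names(x), c("package_version", "seed", "config_hash"))) {
    v <- unlist(x[[nm]])
    v <- vapply(v, function(e) {
      if (is.numeric(e)) format(signif(e, 4)) else as.character(e)
    }, "")
    cat(sprintf("  %s: %s\n", nm,
                paste(names(v), v, sep = "=", collapse = ", ")))
  }
  invisible(x)
}
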