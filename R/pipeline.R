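#' Run configuration for the end-to-end pipeline
#'
#' @param preset scenario preset name for synthetic input, or `NULL` when
#'   `particles` is given.
#' @param particles optional [particle_set] to analyse instead of
#'   simulating (states `"closed"`/`"open*"`; ribosome context then needs
#'   `ribosomes`).
#' @param ribosomes optional ribosome [particle_set] for the ETS stage on
#'   ingested data.
#' @param stages character subset of
#'   `c("clusters", "sweep", "orientations", "ribosome", "states")`.
#' @param threshold cluster cut-off, nm.
#' @param sweep_range,sweep_window sweep grid `c(t_min, t_max)` and
#'   half-width, nm.
#' @param n_tomograms tomogram count override for synthetic runs.
#' @param seed global seed; per-stage child seeds are derived from it, so
#'   toggling one stage leaves the others' randomness unchanged.
#' @param out_dir directory for TSV/summary/log output, or `NULL` to skip
#'   writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = "untreated", particles = NULL,
                       ribosomes = NULL,
                       stages = c("clusters", "sweep", "orientations",
                                  "ribosome", "states"),
                       threshold = 20, sweep_range = c(15, 40),
                       sweep_window = 0.5, n_tomograms = NULL,
                       seed = 1, out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(threshold > 0, sweep_window > 0,
            sweep_range[1] <= sweep_range[2])
  structure(
    list(preset = preset, particles = particles, ribosomes = ribosomes,
         stages = stages, threshold = threshold, sweep_range = sweep_range,
         sweep_window = sweep_window, n_tomograms = n_tomograms,
         seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full spatial-analysis pipeline
#'
#' Orchestrates simulate-or-ingest, cluster tracing, the threshold sweep,
#' neighbour-orientation analysis with the uniformity test, ribosome
#' exit-tunnel-side enrichment, and duty-cycle state accounting, into one
#' report bundle. Deterministic given `rc$seed`: one global seed fans out
#' to fixed per-stage child seeds. If `rc$out_dir` is set, per-stage TSVs,
#' a `summary.json` and a key=value `run.log` are written there.
#'
#' @param rc a [run_config()].
#' @return list of class `pipeline_report`: `config` echo, `particles`,
#'   `clusters`, `cluster_summary`, `sweep`, `orientation` (samples +
#'   test), `ets`, `states`, and `summary` (flat named list of headline
#'   numbers).
#' @export
run_pipeline <- function(rc = run_config()) {
  stopifnot(inherits(rc, "run_config"))
  seeds <- child_seeds(rc$seed, 4)
  t0 <- Sys.time()
  if (is.null(rc$particles)) {
    if (is.null(rc$preset)) stop("stage input: need a preset or particles")
    cfg_args <- list(rc$preset, seed = seeds[1])
    if (!is.null(rc$n_tomograms)) cfg_args$n_tomograms <- rc$n_tomograms
    cfg <- do.call(scenario_preset, cfg_args)
    field <- with_stage("simulate", generate_field(cfg))
    particles <- field$particles
    scene <- if ("ribosome" %in% rc$stages) {
      with_stage("simulate", generate_ribosome_scene(
        do.call(scenario_preset, utils::modifyList(cfg_args,
                                                   list(seed = seeds[2])))
      ))
    } else NULL
    trics <- if (!is.null(scene)) scene$trics else NULL
    ribos <- if (!is.null(scene)) scene$ribosomes else NULL
    truth <- field$truth
  } else {
    particles <- rc$particles
    trics <- rc$particles
    ribos <- rc$ribosomes
    truth <- NULL
    cfg <- NULL
  }
  out <- list(config = rc, particles = particles, truth = truth)
  summary <- list(seed = rc$seed, n_particles = nrow(particles))

  if ("clusters" %in% rc$stages) {
    out$clusters <- with_stage("clusters",
      trace_clusters(particles, threshold = rc$threshold,
                     state_filter = "closed"))
    out$cluster_summary <- cluster_summary(out$clusters)
    summary$n_clusters <- length(out$clusters)
    summary$frac_clustered <- attr(out$cluster_summary, "frac_clustered")
    summary$spacing_mean <- attr(out$cluster_summary, "pooled_mean")
    summary$spacing_sd <- attr(out$cluster_summary, "pooled_sd")
  }
  if ("sweep" %in% rc$stages) {
    out$sweep <- with_stage("sweep",
      threshold_sweep(particles, t_min = rc$sweep_range[1],
                      t_max = rc$sweep_range[2],
                      window = rc$sweep_window, state_filter = "closed"))
    peak <- out$sweep$threshold[which.max(out$sweep$n_clustered)]
    summary$sweep_peak_threshold <- peak
  }
  if ("orientations" %in% rc$stages) {
    if (is.null(out$clusters)) {
      out$clusters <- trace_clusters(particles, threshold = rc$threshold,
                                     state_filter = "closed")
    }
    out$orientation <- with_stage("orientations", {
      if (length(out$clusters) == 0) {
        list(samples = NULL, test = NULL)
      } else {
        smp <- neighbor_orientation_map(particles, out$clusters)
        tst <- if (nrow(smp) >= 10) {
          uniformity_test(smp, seed = seeds[3])
        } else NULL
        list(samples = smp, test = tst)
      }
    })
    if (!is.null(out$orientation$test)) {
      summary$orientation_resultant <- out$orientation$test$statistic
      summary$orientation_p <- out$orientation$test$p_value
    }
  }
  if ("ribosome" %in% rc$stages && !is.null(ribos)) {
    out$ets <- with_stage("ribosome",
      ets_enrichment(trics, ribos, seed = seeds[4]))
    overall <- sum(out$ets$by_state$n * out$ets$by_state$ets_fraction) /
      sum(out$ets$by_state$n)
    summary$ets_fraction <- overall
    summary$ets_n_pairs <- out$ets$n_paired
  }
  if ("states" %in% rc$stages) {
    out$states <- with_stage("states",
      state_distribution(count_states(particles, label = "run")))
    summary$open_percent <- attr(out$states, "open_percent")
    summary$closed_percent <- attr(out$states, "closed_percent")
  }
  summary$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$summary <- summary
  class(out) <- "pipeline_report"
  if (!is.null(rc$out_dir)) write_report(out, rc$out_dir)
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rc <- report$config
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_particle_table(report$particles, file.path(dir, "particles.tsv"),
                       dialect = "delimited")
  if (!is.null(report$clusters)) {
    tsv(as.data.frame(report$clusters), "clusters.tsv")
    tsv(as.data.frame(report$cluster_summary), "cluster_summary.tsv")
  }
  if (!is.null(report$sweep)) tsv(report$sweep, "sweep.tsv")
  if (!is.null(report$orientation$samples)) {
    tsv(report$orientation$samples, "orientations.tsv")
  }
  if (!is.null(report$ets)) {
    tsv(report$ets$pairs, "ets_pairs.tsv")
    tsv(report$ets$by_state, "ets_by_state.tsv")
  }
  if (!is.null(report$states)) tsv(report$states, "states.tsv")
  # flat structured summary; values unboxed scalars
  summ <- report$summary
  json <- paste0(
    "{\n",
    paste(sprintf('  "%s": %s', names(summ), vapply(summ, function(v) {
      if (is.character(v)) sprintf('"%s"', v) else
        format(v, digits = 12, scientific = FALSE)
    }, character(1))), collapse = ",\n"),
    "\n}\n"
  )
  writeLines(json, file.path(dir, "summary.json"))
  log <- c(
    sprintf("stage=config seed=%s stages=%s threshold=%g window=%g",
            format(rc$seed), paste(rc$stages, collapse = ","),
            rc$threshold, rc$sweep_window),
    sprintf("stage=versions r=%s package=%s", getRversion(),
            as.character(utils::packageVersion("tomospat"))),
    sprintf("stage=done wall_time_s=%.2f", summ$wall_time_s)
  )
  writeLines(log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (is.numeric(v)) format(v, digits = 6) else v))
  }
  invisible(x)
}
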