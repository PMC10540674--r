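#' Pipeline configuration
#'
#' Bundles every tunable of the cohort pipeline: input (a directory
#' written by [write_cohort()], or an in-memory simulation spec), output
#' directory, detection parameters (used when the manifest points at
#' voltage trace files), microstructure boundaries, SPT windows and the
#' phenotype cutoff, and QC thresholds. Configs serialize to YAML and
#' reload to an equivalent run.
#'
#' @param input_dir cohort directory (`events.csv` + `manifest.csv`), or
#'   `NULL` when `simulate` is given.
#' @param output_dir run directory for tables, QC report and provenance.
#' @param simulate optional list passed to [simulate_cohort()]
#'   (`n_mice`, `nights`, `preset`, `seed`, ...) to generate the input.
#' @param detection a [detection_params()].
#' @param ili_boundaries classification boundaries (s).
#' @param max_ili,min_licks_bout bout criteria.
#' @param bin_width temporal bin width (s).
#' @param switch_window,pause memory-metric parameters (s).
#' @param cutoff phenotype cutoff (%).
#' @param qc_min_licks,qc_resid_threshold QC thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir,
                            simulate = NULL,
                            detection = detection_params(),
                            ili_boundaries = c(0.180, 0.320, 1.000),
                            max_ili = 1.000, min_licks_bout = 4,
                            bin_width = 1800, switch_window = 60,
                            pause = 300, cutoff = 70,
                            qc_min_licks = 50, qc_resid_threshold = 3) {
  if (is.null(input_dir) && is.null(simulate)) {
    stop("either input_dir or simulate must be given", call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop(sprintf("input_dir not found: %s", input_dir), call. = FALSE)
  }
  structure(list(
    input_dir = input_dir, output_dir = output_dir, simulate = simulate,
    detection = detection, ili_boundaries = ili_boundaries,
    max_ili = max_ili, min_licks_bout = min_licks_bout,
    bin_width = bin_width, switch_window = switch_window, pause = pause,
    cutoff = cutoff, qc_min_licks = qc_min_licks,
    qc_resid_threshold = qc_resid_threshold
  ), class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns an equivalent `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$detection <- unclass(x$detection)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  det <- do.call(detection_params, x$detection)
  x$detection <- NULL
  x$ili_boundaries <- as.numeric(x$ili_boundaries)
  do.call(pipeline_config, c(x, list(detection = det)))
}

#' Run the full SPT analysis pipeline over a cohort
#'
#' One call from a cohort of event streams (or raw voltage traces, or a
#' simulation spec) to QC'd per-session and per-mouse metric tables:
#' detection (when traces are given), double-peak cleaning,
#' microstructure and SPT metrics per session, volume-versus-lick QC with
#' automatic exclusion, per-mouse night averaging with phenotype
#' classification for post-stress conditions, and a cohort summary. The
#' run is deterministic given inputs and config; a provenance file
#' records the config, package version and per-session
#' inclusion/exclusion with reasons. Any stage failure aborts with a
#' stage-named error and leaves a `FAILED` marker in the run directory.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the run tables: `session_table`,
#'   `mouse_table`, `summary_table`, `qc` (the [qc_cohort()] report) and
#'   `output_dir`. Tables are also written as CSV under
#'   `config$output_dir` (`session_metrics.csv`, `mouse_results.csv`,
#'   `cohort_summary.csv`, `qc_points.csv`, `exclusions.csv`,
#'   `provenance.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 failed_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("load", {
    if (!is.null(config$simulate)) do.call(simulate_cohort, config$simulate)
    else read_cohort(config$input_dir)
  })
  manifest <- cohort$manifest

  # detection stage: only when the manifest points at raw voltage traces
  if (!is.null(manifest$trace_file)) {
    cohort$sessions <- stage("detect", {
      lapply(seq_len(nrow(manifest)), function(i) {
        mrow <- manifest[i, ]
        rec <- read_recording(
          file.path(config$input_dir %||% ".", mrow$trace_file),
          metadata = list(volumes = c(water = mrow$vol_water_ml,
                                      sucrose = mrow$vol_sucrose_ml))
        )
        tr <- detect_licks(rec, config$detection)
        list(water = tr$water, sucrose = tr$sucrose,
             volumes = rec$metadata$volumes)
      })
    })
    names(cohort$sessions) <- manifest$session
  }

  metrics <- stage("metrics", {
    lapply(seq_len(nrow(manifest)), function(i) {
      mrow <- manifest[i, ]
      s <- cohort$sessions[[mrow$session]]
      w <- remove_double_peaks(s$water, config$detection$min_ili_s)
      su <- remove_double_peaks(s$sucrose, config$detection$min_ili_s)
      session_metrics(
        w, su, volumes = s$volumes,
        session_length = mrow$session_length %||% 57600,
        dark_onset = mrow$dark_onset %||% 0,
        dark_offset = mrow$dark_offset %||% 43200,
        bin_width = config$bin_width, max_ili = config$max_ili,
        min_licks_bout = config$min_licks_bout,
        switch_window = config$switch_window, pause = config$pause
      )
    })
  })
  names(metrics) <- manifest$session

  qc <- stage("qc", {
    qc_cohort(qc_points(cohort), min_licks = config$qc_min_licks,
              resid_threshold = config$qc_resid_threshold)
  })
  excluded <- qc$exclusions$session

  session_table <- stage("session_table", {
    do.call(rbind, lapply(manifest$session, function(id) {
      m <- metrics[[id]]
      bs <- m$bottle_stats
      wide <- data.frame(session = id)
      for (b in bs$bottle) {
        r <- bs[bs$bottle == b, ]
        for (cn in setdiff(names(bs), "bottle")) {
          wide[[paste(b, cn, sep = "_")]] <- r[[cn]]
        }
      }
      wide$switch_w_to_s <- unname(m$switches["water_to_sucrose"])
      wide$switch_s_to_w <- unname(m$switches["sucrose_to_water"])
      wide$preference_volume <- m$preference_volume
      wide$preference_licks <- m$preference_licks
      wide$included <- !(id %in% excluded)
      wide
    }))
  })
  session_table <- merge(
    manifest[, c("session", "mouse_id", "sex", "night", "condition",
                 "sucrose_side")],
    session_table, by = "session", sort = TRUE
  )

  mouse_table <- stage("mouse_results", {
    do.call(rbind, lapply(unique(manifest$mouse_id), function(mid) {
      rows <- manifest[manifest$mouse_id == mid, ]
      rows <- rows[order(rows$night), ]
      res <- average_nights(
        metrics[rows$session],
        include = !(rows$session %in% excluded),
        mouse_id = mid, sex = rows$sex[1], condition = rows$condition[1]
      )
      phen <- if (isTRUE(rows$post_stress[1])) {
        classify_phenotype(res$final_preference, config$cutoff)
      } else "n/a"
      d <- data.frame(
        mouse_id = mid, sex = res$sex, condition = res$condition,
        phenotype = phen,
        final_preference = res$final_preference,
        final_preference_licks = res$final_preference_licks,
        n_nights_included = res$n_nights_included,
        single_night = res$single_night, missing = res$missing
      )
      if (!res$missing) {
        for (b in res$bottle_stats$bottle) {
          r <- res$bottle_stats[res$bottle_stats$bottle == b, ]
          for (cn in setdiff(names(res$bottle_stats), "bottle")) {
            d[[paste(b, cn, sep = "_")]] <- r[[cn]]
          }
        }
        d$switch_w_to_s <- unname(res$switches["water_to_sucrose"])
        d$switch_s_to_w <- unname(res$switches["sucrose_to_water"])
      }
      d
    }))
  })

  summary_table <- stage("summary", summarize_cohort(mouse_table))

  stage("write", {
    write.csv(session_table, file.path(out, "session_metrics.csv"),
              row.names = FALSE)
    write.csv(mouse_table, file.path(out, "mouse_results.csv"),
              row.names = FALSE)
    write.csv(summary_table, file.path(out, "cohort_summary.csv"),
              row.names = FALSE)
    write.csv(qc$points, file.path(out, "qc_points.csv"), row.names = FALSE)
    write.csv(qc$exclusions, file.path(out, "exclusions.csv"),
              row.names = FALSE)
    cfg_path <- file.path(out, "config.yaml")
    write_pipeline_config(config, cfg_path)
    prov <- list(
      package = "lickspt",
      version = as.character(packageVersion("lickspt")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config_md5 = unname(tools::md5sum(cfg_path)),
      n_sessions = nrow(manifest),
      included = manifest$session[!(manifest$session %in% excluded)],
      exclusions = qc$exclusions
    )
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(session_table = session_table, mouse_table = mouse_table,
                 summary_table = summary_table, qc = qc, metrics = metrics,
                 output_dir = out))
}

#' Descriptive cohort summary
#'
#' Group means, SD, SE and n of every numeric per-mouse metric, by the
#' requested grouping keys (those present in the table). Purely
#' descriptive: inferential statistics are left to external tooling.
#'
#' @param mouse_table per-mouse results table (as produced by
#'   [run_pipeline()], one row per mouse).
#' @param by grouping columns; defaults to condition, sex and phenotype.
#' @return Long data.frame: grouping keys, `metric`, `mean`, `sd`, `se`,
#'   `n`. Empty groups are omitted.
#' @export
summarize_cohort <- function(mouse_table,
                             by = c("condition", "sex", "phenotype")) {
  if (!nrow(mouse_table)) stop("need >= 1 mouse result", call. = FALSE)
  by <- intersect(by, names(mouse_table))
  num_cols <- names(mouse_table)[vapply(mouse_table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("n_nights_included"))
  groups <- if (length(by)) {
    interaction(mouse_table[by], drop = TRUE, sep = "|")
  } else factor(rep("all", nrow(mouse_table)))
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- mouse_table[groups == g, , drop = FALSE]
    do.call(rbind, lapply(num_cols, function(cn) {
      v <- sub[[cn]]
      v <- v[!is.na(v)]
      if (!length(v)) return(NULL)
      key <- sub[1, by, drop = FALSE]
      rownames(key) <- NULL
      cbind(key, data.frame(
        metric = cn, mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
        se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v)
      ))
    }))
  }))
  rownames(out) <- NULL
  out
}
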