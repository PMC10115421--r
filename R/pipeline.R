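#' Match trial counts across the four condition cells
#'
#' All analyses run on the same number of trials per cell: each cell is
#' subsampled (uniformly, without replacement, seeded) to the minimum cell
#' count. Cells already at the minimum are kept unchanged.
#'
#' @param cell_indices named list (liLE, liHE, hiLE, hiHE) of trial index
#'   vectors.
#' @param seed RNG seed; the same seed always yields the same subsets.
#' @return Named list of matched index vectors, all of equal length.
#' @export
match_trials <- function(cell_indices, seed = 1) {
  if (!setequal(names(cell_indices), condition_cells()))
    stop("cell_indices must name all four cells")
  sizes <- lengths(cell_indices)
  if (any(sizes == 0))
    stop("empty condition cell(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "))
  m <- min(sizes)
  with_seed(seed, {
    lapply(cell_indices[condition_cells()], function(ix) {
      if (length(ix) == m) ix else sort(sample(ix, m))
    })
  })
}

#' Exclude subjects with too few matched trials
#'
#' @param matched_counts named (by subject) vector of per-cell matched
#'   trial counts.
#' @param threshold minimum matched trials to retain a subject (default
#'   10).
#' @return Names (or indices) of retained subjects.
#' @export
exclude_low_trial_subjects <- function(matched_counts, threshold = 10) {
  keep <- matched_counts >= threshold
  if (!any(keep)) stop("all subjects excluded at threshold ", threshold)
  if (is.null(names(matched_counts))) which(keep) else names(matched_counts)[keep]
}

#' Pipeline configuration
#'
#' Collects everything \code{\link{run_pipeline}} needs: the simulation
#' config (or a path to a serialized epoch container), the analysis bands
#' and window, beamformer settings, trial-matching seed and Bayes-factor
#' engine settings. Can be read from a YAML file with
#' \code{\link{read_pipeline_config}}.
#'
#' @param sim a \code{\link{simulation_config}}, or NULL when
#'   \code{epochs_path} is given.
#' @param design a \code{\link{condition_design}}.
#' @param epochs_path optional path to a container written by
#'   \code{\link{write_epochs}}.
#' @param bands list of \code{\link{band_spec}}.
#' @param window analysis window, seconds.
#' @param sensor_space if TRUE, project the simulated ROI signals through a
#'   random leadfield and reconstruct them with frequency-specific LCMV
#'   beamformers before analysis.
#' @param n_sensors sensors for the sensor-space route.
#' @param reg beamformer regularization fraction.
#' @param min_trials subject-exclusion threshold on matched trial counts.
#' @param mvar_order MVAR order for directed analysis.
#' @param directed_all_pairs if TRUE, run the directed analysis on every
#'   pair rather than only on pairs flagged by the connectivity ANOVA.
#' @param bf_method "topdown" or "inclusion" (see
#'   \code{\link{bf_rmanova_2x2}}).
#' @param seed master seed; stage seeds derive from it.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = simulation_config(), design = condition_design(),
                            epochs_path = NULL, bands = make_bands(),
                            window = c(0, 1), sensor_space = FALSE,
                            n_sensors = 32, reg = 0.05, min_trials = 10,
                            mvar_order = 5, directed_all_pairs = FALSE,
                            bf_method = "topdown", seed = 1) {
  if (is.null(sim) && is.null(epochs_path))
    stop("supply either a simulation config or an epochs path")
  if (!is.null(epochs_path) && !file.exists(epochs_path))
    stop("epochs_path does not exist: ", epochs_path)
  structure(
    list(sim = sim, design = design, epochs_path = epochs_path, bands = bands,
         window = window, sensor_space = sensor_space, n_sensors = n_sensors,
         reg = reg, min_trials = min_trials, mvar_order = mvar_order,
         directed_all_pairs = directed_all_pairs, bf_method = bf_method,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the arguments of
#' \code{\link{pipeline_config}} and \code{\link{simulation_config}}
#' (under a \code{sim:} block); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim
  y$sim <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  sim <- if (is.null(simargs)) simulation_config()
         else do.call(simulation_config, simargs)
  do.call(pipeline_config, c(list(sim = sim), y))
}

# BF table over a set of features: one bf_rmanova_2x2 + pattern call per
# feature, from a long table with subject/condition/value columns.
bf_table <- function(tab, featcols, value, method = "topdown") {
  key <- do.call(paste, tab[featcols])
  feats <- unique(tab[featcols])
  out <- data.frame(feats,
                    bf_intensity = NA_real_, bf_expectation = NA_real_,
                    bf_interaction = NA_real_, pattern = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(feats))) {
    sub <- tab[key == do.call(paste, feats[i, , drop = FALSE]), ]
    res <- bf_rmanova_2x2(cell_matrix(sub, value), method = method)
    out$bf_intensity[i] <- res$bf["intensity"]
    out$bf_expectation[i] <- res$bf["expectation"]
    out$bf_interaction[i] <- res$bf["interaction"]
    out$pattern[i] <- classify_pattern(res)
  }
  class(out) <- c("bf_table", "data.frame")
  out
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) epochs; optionally project to sensors and beamform
#' back per band; match trials across cells and drop low-trial subjects;
#' compute band power and dwPLI tables; run Bayes-factor rmANOVAs and
#' pattern calls on ratings, power and connectivity; run the directed
#' (PDC asymmetry) analysis on flagged pairs — with all trials for pairs
#' flagged by a main effect and mismatch trials only for pairs flagged by
#' an interaction — and test the group asymmetry against zero; and compare
#' power-based against connectivity-based logistic models.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Object of class \code{painconn_results} with components
#'   \code{ratings}, \code{power}, \code{connectivity}, \code{directed},
#'   \code{model_comparison}, \code{truth} (when simulated) and
#'   \code{provenance}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- data ---------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$epochs_path)) {
    epochs <- stage("load", read_epochs(config$epochs_path))
    ratings <- NULL
  } else {
    simout <- stage("simulate", simulate_epochs(config$sim, config$design))
    epochs <- simout$epochs
    truth <- simout$truth
    ratings <- stage("simulate", simulate_ratings(config$sim, config$design))
  }

  # --- optional sensor projection + beamforming ---------------------------
  if (config$sensor_space) {
    epochs <- stage("beamform", {
      lf <- random_leadfield(config$n_sensors,
                             epochs[[1]]$channels,
                             seed = derive_seed(config$seed, "leadfield"))
      lapply(epochs, function(ep) {
        sens <- project_to_sensors(ep, lf, sensor_noise_sd = 0.1,
                                   seed = derive_seed(config$seed, "sensornoise"))
        # beamform per band and sum the band-limited reconstructions
        recon <- NULL
        for (b in names(config$bands)) {
          C <- band_covariance(sens, config$bands[[b]])
          flt <- lcmv_filter(lf, C, reg = config$reg, band = config$bands[[b]])
          rb <- apply_filter(sens, flt)
          recon <- if (is.null(recon)) rb$data else recon + rb$data
        }
        epoch_array(recon, rate = ep$rate, time = ep$time, labels = ep$labels,
                    space = "roi", channels = ep$channels)
      })
    })
  }

  # --- trial matching and subject exclusion -------------------------------
  epochs <- stage("trial_match", {
    lapply(seq_along(epochs), function(s) {
      ep <- epochs[[s]]
      idx <- split(seq_along(ep$labels),
                   factor(ep$labels, levels = condition_cells()))
      matched <- match_trials(idx, seed = derive_seed(config$seed,
                                                      paste0("match", s)))
      subset_epochs(ep, trials = sort(unlist(matched)))
    })
  })
  counts <- vapply(epochs, function(ep) sum(ep$labels == "liLE"), 0L)
  names(counts) <- seq_along(epochs)
  keep <- stage("exclude", exclude_low_trial_subjects(counts, config$min_trials))
  keep <- as.integer(keep)
  epochs <- epochs[keep]
  if (!is.null(ratings)) ratings <- ratings[ratings$subject %in% keep, ]

  # --- ratings ------------------------------------------------------------
  rating_res <- NULL
  if (!is.null(ratings)) rating_res <- stage("stats", {
    res <- bf_rmanova_2x2(cell_matrix(ratings, "rating"), method = config$bf_method)
    list(bf = res, pattern = classify_pattern(res), table = ratings)
  })

  # --- band power + rmANOVA ----------------------------------------------
  power_res <- stage("power", {
    tab <- power_table(epochs, config$bands, config$window)
    list(table = tab,
         bf = bf_table(tab, c("roi", "band"), "power", config$bf_method))
  })

  # --- dwPLI + rmANOVA ----------------------------------------------------
  conn_res <- stage("connectivity", {
    tab <- connectivity_table(epochs, config$bands, config$window)
    list(table = tab,
         bf = bf_table(tab, c("roi_a", "roi_b", "band"), "dwpli",
                       config$bf_method))
  })

  # --- directed analysis on flagged pairs ---------------------------------
  directed_res <- stage("directed", {
    cb <- conn_res$bf
    flag_main <- cb$bf_intensity > 3 | cb$bf_expectation > 3
    flag_int <- cb$bf_interaction > 3
    sel <- if (config$directed_all_pairs) rep(TRUE, nrow(cb))
           else flag_main | flag_int
    out <- list()
    for (i in which(sel)) {
      filt <- if (flag_int[i] && !flag_main[i]) "mismatch_only" else "all_trials"
      da <- directed_analysis(epochs, c(cb$roi_a[i], cb$roi_b[i]),
                              config$bands[[cb$band[i]]], trial_filter = filt,
                              order = config$mvar_order, window = config$window)
      # the one-sample BF needs at least 5 nonzero scores; smaller groups
      # get an NA BF rather than a hard failure
      ok <- sum(da$asymmetry != 0, na.rm = TRUE) >= 5
      bf <- if (ok) bf_onesample(da$asymmetry)
            else list(bf = NA_real_, mcse = NA_real_)
      out[[paste(cb$roi_a[i], cb$roi_b[i], cb$band[i], sep = "_")]] <-
        list(pair = c(cb$roi_a[i], cb$roi_b[i]), band = cb$band[i],
             trial_filter = filt, scores = da,
             mean_asymmetry = mean(da$asymmetry), bf = bf$bf, mcse = bf$mcse)
    }
    out
  })

  # --- model comparison ---------------------------------------------------
  mc <- stage("compare", run_model_comparison(power_res$table, conn_res$table))

  structure(
    list(ratings = rating_res, power = power_res, connectivity = conn_res,
         directed = directed_res, model_comparison = mc, truth = truth,
         provenance = list(
           config_hash = config_hash(config), seed = config$seed,
           n_subjects = length(epochs),
           matched_trials_per_cell = unname(counts[keep]),
           package_version = as.character(utils::packageVersion("painconn")),
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "painconn_results"
  )
}

#' @export
print.painconn_results <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<painconn_results> %d subjects, %d matched trials/cell, seed %d (config %s)\n",
              p$n_subjects, p$matched_trials_per_cell[1], p$seed, p$config_hash))
  if (!is.null(x$ratings))
    cat(sprintf("Ratings: pattern '%s' (BF int %.3g, exp %.3g, inter %.3g)\n",
                x$ratings$pattern, x$ratings$bf$bf["intensity"],
                x$ratings$bf$bf["expectation"], x$ratings$bf$bf["interaction"]))
  pb <- x$power$bf
  cat(sprintf("Power: %d/%d ROI-band features flagged (pattern != none)\n",
              sum(pb$pattern %in% c("intensity", "expectation", "PE", "multiple")),
              nrow(pb)))
  cb <- x$connectivity$bf
  cat(sprintf("Connectivity: %d/%d pair-band features flagged\n",
              sum(cb$pattern %in% c("intensity", "expectation", "PE", "multiple")),
              nrow(cb)))
  cat(sprintf("Directed: %d pair(s) analysed\n", length(x$directed)))
  for (nm in names(x$directed)) {
    d <- x$directed[[nm]]
    cat(sprintf("  %s -> %s (%s, %s): mean asymmetry %+.3f, BF10 = %.3g\n",
                d$pair[1], d$pair[2], d$band, d$trial_filter,
                d$mean_asymmetry, d$bf))
  }
  print(x$model_comparison)
  invisible(x)
}

#' @export
summary.painconn_results <- function(object, ...) {
  cat("Pattern calls (power features):\n")
  print(table(object$power$bf$pattern))
  cat("\nPattern calls (connectivity features):\n")
  print(table(object$connectivity$bf$pattern))
  cat("\n")
  print(object)
  invisible(object)
}

#' Write the result tables of a pipeline run
#'
#' Writes the power, connectivity and Bayes-factor tables, directed
#' results and model-comparison evidences as delimited text files plus a
#' YAML run manifest with provenance (config hash, seed, versions).
#'
#' @param results a \code{\link{run_pipeline}} result.
#' @param dir output directory (created if needed).
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(results$power$table, "power_table.csv")
  wr(results$power$bf, "power_bf.csv")
  wr(results$connectivity$table, "connectivity_table.csv")
  wr(results$connectivity$bf, "connectivity_bf.csv")
  if (!is.null(results$ratings)) wr(results$ratings$table, "ratings.csv")
  if (length(results$directed)) {
    dd <- do.call(rbind, lapply(names(results$directed), function(nm) {
      d <- results$directed[[nm]]
      data.frame(pair = nm, band = d$band, trial_filter = d$trial_filter,
                 mean_asymmetry = d$mean_asymmetry, bf = d$bf)
    }))
    wr(dd, "directed.csv")
  }
  mcdf <- do.call(rbind, lapply(names(results$model_comparison), function(ct)
    data.frame(contrast = ct,
               bf_pow_vs_conn = results$model_comparison[[ct]]$bf_pow_vs_conn)))
  wr(mcdf, "model_comparison.csv")
  yaml::write_yaml(results$provenance, file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}
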