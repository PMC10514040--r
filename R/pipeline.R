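#' Pipeline configuration
#'
#' Collects every tunable of the simulate -> preprocess -> connectivity ->
#' graph -> stats -> classify chain. Defaults reproduce the study design:
#' 64-channel montage, 256 Hz, 20 four-second epochs, six bands, density
#' grid 0.01-0.50 (step 0.01) with features at 0.08, 100 surrogates at
#' alpha 0.05, FDR 0.05, five classifiers under LOO-CV.
#'
#' @param out_dir results directory.
#' @param montage `"biosemi64"`, `"demo"`, or a [montage_spec].
#' @param bands band names (see [eeg_bands()]).
#' @param moods,target_frequencies condition cells to simulate/analyze.
#' @param n_ls,n_hs cohort sizes.
#' @param fs,n_epochs,epoch_len recording geometry.
#' @param kappa_within,kappa_between,subject_sd,snr_db generator coupling
#'   parameters (see [coupling_plan()]).
#' @param densities proportional threshold grid.
#' @param feature_density density whose metrics feed classification; must
#'   be on the grid.
#' @param surrogate_M,surrogate_alpha surrogate-null parameters.
#' @param fdr_q edge-family FDR level.
#' @param p_threshold raw node/global significance threshold.
#' @param strict_p stricter nodal threshold exported separately.
#' @param classifiers classifier names for [loo_cv()].
#' @param n_features top-|t| features per training fold.
#' @param phase_source `"phases"` (generator ground-truth instantaneous
#'   phases, the default for synthetic cohorts) or `"signal"` (zero-phase
#'   band filter + Hilbert on the waveforms, the route used for recorded
#'   data). The generator's per-sample phase jitter is spectrally broadband,
#'   so narrowband filtering removes most of it and saturates waveform-route
#'   PLV; see the methods vignette.
#' @param write_matrices write one connectivity CSV per subject x cell x
#'   band (off by default; can be many files).
#' @param seed root seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "ganznet-results",
                            montage = "biosemi64",
                            bands = eeg_bands()$band,
                            moods = ganzfeld_moods(),
                            target_frequencies = ganzfeld_frequencies(),
                            n_ls = 29, n_hs = 14,
                            fs = 256, n_epochs = 20, epoch_len = 4,
                            kappa_within = 2, kappa_between = 0.4,
                            subject_sd = 0.2, snr_db = 0,
                            densities = seq(0.01, 0.50, 0.01),
                            feature_density = 0.08,
                            surrogate_M = 100, surrogate_alpha = 0.05,
                            fdr_q = 0.05, p_threshold = 0.05,
                            strict_p = 0.001,
                            classifiers = c("dt", "knn", "lda", "svm",
                                            "rusboost"),
                            n_features = 10,
                            phase_source = "phases",
                            write_matrices = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  cfg$montage_name <- if (is.character(montage)) montage else "custom"
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (!any(abs(cfg$densities - cfg$feature_density) < 1e-9))
    stop("feature_density (", cfg$feature_density,
         ") is not on the density grid")
  if (1 / (cfg$surrogate_M + 1) >= cfg$surrogate_alpha)
    stop("surrogate_M too small for alpha = ", cfg$surrogate_alpha)
  bad <- setdiff(cfg$bands, eeg_bands()$band)
  if (length(bad)) stop("unknown bands: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

resolve_montage <- function(m) {
  if (inherits(m, "montage_spec")) return(m)
  switch(m, biosemi64 = biosemi64_montage(), demo = demo_montage(),
         stop("unknown montage: ", m))
}

#' Read/write a pipeline configuration as YAML
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  lst <- unclass(cfg)
  lst$montage <- cfg$montage_name
  lst$montage_name <- NULL
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(pipeline_config, lst)
}

# polynomial string hash, reported as 8 hex digits (provenance tag);
# modular arithmetic kept exact in doubles
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg)[order(names(unclass(cfg)))])
  h <- 216613626
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a recording as a delimited matrix plus JSON sidecar
#'
#' The data file is a headerless CSV of channels x (samples * epochs)
#' values; the sidecar (`<path>.json`) stores rate, labels, epoch geometry
#' and condition metadata.
#'
#' @param rec an `epoched_recording`.
#' @param path data file path (sidecar written next to it).
#' @return `read_delimited` returns an `epoched_recording`.
#' @export
write_delimited <- function(rec, path) {
  d <- dim(rec$data)
  flat <- matrix(rec$data, d[1], d[2] * d[3])
  utils::write.table(flat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = rec$fs,
               labels = if (!is.null(rec$montage)) rec$montage$labels else
                 paste0("Ch", seq_len(d[1])),
               n_epochs = d[3], samples_per_epoch = d[2],
               condition = rec$condition, group = rec$group)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_delimited
#' @param montage optional [montage_spec] validated against stored labels.
#' @export
read_delimited <- function(path, montage = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = ","))
  data <- array(flat, dim = c(nrow(flat), meta$samples_per_epoch,
                              meta$n_epochs),
                dimnames = list(meta$labels, NULL, NULL))
  if (!is.null(montage)) {
    bad <- c(setdiff(meta$labels, montage$labels),
             setdiff(montage$labels, meta$labels))
    if (length(bad))
      stop("channel labels do not match the montage; offenders: ",
           paste(bad, collapse = ", "))
    data <- data[match(montage$labels, meta$labels), , , drop = FALSE]
  }
  structure(list(data = data, fs = meta$fs,
                 montage = montage %||% montage_spec(meta$labels),
                 condition = as.list(meta$condition),
                 group = meta$group %||% NA_character_),
            class = "epoched_recording")
}

#' Read a recording from disk
#' @param path file path.
#' @param format `"edf"` or `"delimited"`; guessed from the extension by
#'   default.
#' @param montage optional [montage_spec] to validate against.
#' @return an `epoched_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "delimited"),
                           montage = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else
      "delimited"
  switch(format, edf = read_edf(path, montage),
         delimited = read_delimited(path, montage))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Streams subjects through simulate -> band connectivity (zero-phase FIR,
#' Hilbert phase, epoch-averaged PLV, surrogate pruning) -> graph metrics
#' over the density sweep -> group statistics (edge / node / global) ->
#' LOO-CV classification, writing delimited tables and provenance metadata
#' under `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param stages furthest stage to run: `"connectivity"`, `"graph"`,
#'   `"stats"`, or `"classify"` (default: everything).
#' @param quiet suppress progress messages.
#' @return list with `design`, `entries` (per subject x cell x band graph
#'   metrics), `edge_stats`, `node_stats`, `global_stats`,
#'   `classification`, `out_dir`.
#' @export
run_pipeline <- function(cfg, stages = "classify", quiet = FALSE) {
  validate_config(cfg)
  stage_order <- c("connectivity", "graph", "stats", "classify")
  last <- match(match.arg(stages, stage_order), stage_order)
  montage <- resolve_montage(cfg$montage)
  plan <- coupling_plan(montage, kappa_within = cfg$kappa_within,
                        kappa_between = cfg$kappa_between,
                        bands = cfg$bands, subject_sd = cfg$subject_sd,
                        snr_db = cfg$snr_db, seed = cfg$seed)
  design <- cohort_design(cfg$n_ls, cfg$n_hs, cfg$moods,
                          cfg$target_frequencies, seed = cfg$seed,
                          subject_sd = cfg$subject_sd)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) message(...)

  conn_dir <- file.path(cfg$out_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  entries <- list()
  edge_rows <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    rec <- generate_subject(
      plan, fs = cfg$fs, n_epochs = cfg$n_epochs,
      epoch_len = cfg$epoch_len, group = row$group,
      condition = list(mood = row$mood,
                       target_frequency = row$target_frequency),
      seed = row$cell_seed, subject_multiplier = row$multiplier,
      return_phases = identical(cfg$phase_source, "phases"))
    for (band in cfg$bands) {
      phases <- band_phases(rec, band, source = cfg$phase_source)
      plv <- epoch_averaged_plv(phases)
      plv$band <- band
      plv$condition <- rec$condition
      pruned <- surrogate_prune(plv, phases,
                                M = cfg$surrogate_M,
                                alpha = cfg$surrogate_alpha,
                                seed = derive_seed(cfg$seed, row$subject,
                                                   row$mood, band,
                                                   row$target_frequency * 10))
      key <- paste(row$subject, row$mood, row$target_frequency, band,
                   sep = "_")
      if (cfg$write_matrices)
        utils::write.table(pruned$values,
                           file.path(conn_dir, paste0("plv_", key, ".csv")),
                           sep = ",", col.names = NA)
      edge_rows[[key]] <- list(subject = row$subject, group = row$group,
                               mood = row$mood,
                               target_frequency = row$target_frequency,
                               band = band,
                               edges = pruned$values[upper.tri(pruned$values)])
      if (last >= 2) {
        sweep_res <- suppressWarnings(
          metrics_over_density_sweep(pruned$values, cfg$densities,
                                     cfg$feature_density))
        entries[[key]] <- list(
          subject = row$subject, group = row$group, mood = row$mood,
          target_frequency = row$target_frequency, band = band,
          metrics = sweep_res$feature_metrics,
          ge_by_density = vapply(sweep_res$per_density, function(g)
            if (is.null(g)) NA_real_ else g$ge, numeric(1)))
      }
    }
    say("subject ", row$subject, " ", row$mood, " ",
        row$target_frequency, " Hz done (", i, "/", nrow(design), ")")
  }
  edge_labels <- {
    ut <- which(upper.tri(diag(length(montage$labels))), arr.ind = TRUE)
    paste(montage$labels[ut[, 1]], montage$labels[ut[, 2]], sep = "-")
  }

  graph_dir <- file.path(cfg$out_dir, "graphs")
  if (last >= 2) {
    dir.create(graph_dir, showWarnings = FALSE)
    node_tab <- do.call(rbind, lapply(entries, function(e)
      data.frame(subject = e$subject, group = e$group, mood = e$mood,
                 target_frequency = e$target_frequency, band = e$band,
                 density = cfg$feature_density,
                 node = names(e$metrics$strength),
                 strength = unname(e$metrics$strength),
                 cc = unname(e$metrics$cc), row.names = NULL)))
    utils::write.table(node_tab, file.path(graph_dir, "node_metrics.csv"),
                       sep = ",", row.names = FALSE)
    ge_tab <- do.call(rbind, lapply(entries, function(e)
      data.frame(subject = e$subject, group = e$group, mood = e$mood,
                 target_frequency = e$target_frequency, band = e$band,
                 density = cfg$densities, ge = unname(e$ge_by_density),
                 row.names = NULL)))
    utils::write.table(ge_tab, file.path(graph_dir, "global_metrics.csv"),
                       sep = ",", row.names = FALSE)
  }

  edge_stats <- node_stats <- global_stats <- NULL
  if (last >= 3) {
    stats_dir <- file.path(cfg$out_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    cells <- unique(design[, c("mood", "target_frequency")])
    edge_stats <- list(); node_stats <- list(); global_stats <- list()
    for (ci in seq_len(nrow(cells))) {
      mood <- cells$mood[ci]; tf <- cells$target_frequency[ci]
      for (band in cfg$bands) {
        sel <- Filter(function(e) e$mood == mood &&
                        e$target_frequency == tf && e$band == band,
                      edge_rows)
        groups <- vapply(sel, `[[`, "", "group")
        em <- do.call(rbind, lapply(sel, `[[`, "edges"))
        colnames(em) <- edge_labels
        es <- compare_networks(em[groups == "HS", , drop = FALSE],
                               em[groups == "LS", , drop = FALSE],
                               level = "edge", fdr_q = cfg$fdr_q)
        es <- cbind(mood = mood, target_frequency = tf, band = band, es)
        edge_stats[[paste(mood, tf, band)]] <- es

        ent <- Filter(function(e) e$mood == mood &&
                        e$target_frequency == tf && e$band == band, entries)
        gr <- vapply(ent, `[[`, "", "group")
        for (metric in c("strength", "cc")) {
          nm <- do.call(rbind, lapply(ent, function(e) e$metrics[[metric]]))
          ns <- compare_networks(nm[gr == "HS", , drop = FALSE],
                                 nm[gr == "LS", , drop = FALSE],
                                 level = "node_metric",
                                 p_threshold = cfg$p_threshold)
          ns <- cbind(mood = mood, target_frequency = tf, band = band,
                      metric = metric, density = cfg$feature_density, ns)
          node_stats[[paste(mood, tf, band, metric)]] <- ns
        }
        gm <- do.call(rbind, lapply(ent, `[[`, "ge_by_density"))
        colnames(gm) <- format(cfg$densities)
        ok <- colSums(is.na(gm)) == 0
        gs <- compare_networks(gm[gr == "HS", ok, drop = FALSE],
                               gm[gr == "LS", ok, drop = FALSE],
                               level = "global",
                               p_threshold = cfg$p_threshold)
        gs <- cbind(mood = mood, target_frequency = tf, band = band, gs)
        global_stats[[paste(mood, tf, band)]] <- gs
      }
    }
    edge_stats <- do.call(rbind, c(edge_stats, make.row.names = FALSE))
    node_stats <- do.call(rbind, c(node_stats, make.row.names = FALSE))
    global_stats <- do.call(rbind, c(global_stats, make.row.names = FALSE))
    utils::write.table(edge_stats,
                       file.path(stats_dir, "edge_comparisons.csv"),
                       sep = ",", row.names = FALSE)
    utils::write.table(node_stats,
                       file.path(stats_dir, "node_comparisons.csv"),
                       sep = ",", row.names = FALSE)
    utils::write.table(node_stats[node_stats$p < cfg$strict_p, ],
                       file.path(stats_dir, "node_comparisons_strict.csv"),
                       sep = ",", row.names = FALSE)
    utils::write.table(global_stats,
                       file.path(stats_dir, "global_comparisons.csv"),
                       sep = ",", row.names = FALSE)
  }

  classification <- NULL
  if (last >= 4) {
    cls_dir <- file.path(cfg$out_dir, "classification")
    dir.create(cls_dir, showWarnings = FALSE)
    classification <- list()
    for (mood in cfg$moods) {
      feats <- assemble_features(entries, mood)
      for (clf in cfg$classifiers) {
        res <- loo_cv(feats, classifier = clf, k = cfg$n_features,
                      seed = derive_seed(cfg$seed, "cv", mood, clf))
        classification[[paste(mood, clf)]] <-
          data.frame(mood = mood, classifier = clf,
                     accuracy = res$metrics$accuracy_pct,
                     sensitivity = res$metrics$sensitivity_pct,
                     specificity = res$metrics$specificity_pct,
                     f1 = res$metrics$f1_2dp,
                     tp = res$confusion["TP"], fn = res$confusion["FN"],
                     tn = res$confusion["TN"], fp = res$confusion["FP"],
                     row.names = NULL)
      }
    }
    classification <- do.call(rbind, c(classification,
                                       make.row.names = FALSE))
    utils::write.table(classification,
                       file.path(cls_dir, "metrics.csv"),
                       sep = ",", row.names = FALSE)
  }

  prov <- list(config_hash = hash, seed = cfg$seed,
               package_version = as.character(
                 utils::packageVersion("ganznet")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  write_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  invisible(list(design = design, entries = entries,
                 edge_stats = edge_stats, node_stats = node_stats,
                 global_stats = global_stats,
                 classification = classification, out_dir = cfg$out_dir))
}
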