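#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations and a global seed. The global seed
#' deterministically derives every per-stage seed (simulation sequences,
#' splitting, training), so a pipeline run is reproducible from one number.
#'
#' @param seed Global integer seed.
#' @param n_sequences Number of simulated time-lapse sequences.
#' @param sim A [sim_config()] template (its seed is overridden per
#'   sequence).
#' @param optics An [optics_config()].
#' @param gt A [gt_config()].
#' @param train A [train_config()].
#' @param max_disp_px,min_len Tracking parameters (see [link_tracks()]).
#' @param data_dir Optional directory of pre-simulated datasets (one
#'   subdirectory per sequence, as written by [write_experiment()]); when
#'   given, ingestion replaces simulation.
#' @param out_dir Optional output directory for intermediates and the JSON
#'   report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_sequences = 8L,
                            sim = sim_config(image_px = 128L, n_cells = 5L),
                            optics = optics_config(),
                            gt = gt_config(),
                            train = train_config(),
                            max_disp_px = 30,
                            min_len = 5,
                            data_dir = NULL,
                            out_dir = NULL) {
  stopifnot(n_sequences >= 3)
  structure(
    list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
         sim = sim, optics = optics, gt = gt, train = train,
         max_disp_px = max_disp_px, min_len = min_len,
         data_dir = data_dir, out_dir = out_dir),
    class = "pipeline_config"
  )
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "phaseviab_stage_error")
  })
}

#' Run the full label-free viability pipeline
#'
#' Chains every stage on simulated (or ingested) data: simulate/ingest ->
#' reconstruct phase from interferograms -> fluorescence-derived ground
#' truth -> sequence-level split -> train the segmenter -> predict held-out
#' frames -> object-based evaluation -> tracking of the test sequences.
#' Writes the JSON report (and intermediates) to `cfg$out_dir` when set.
#'
#' @param cfg A [pipeline_config()].
#' @return A report list: per-stage seeds, training history, object
#'   confusion counts, normalized confusion, precision/recall/F1 (including
#'   `macro_f1_pct`), pixel metrics and track statistics.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- list(
    sim = cfg$seed * 1000L + seq_len(cfg$n_sequences),
    split = cfg$seed + 1L,
    train = cfg$seed + 2L
  )

  experiments <- stage_run("simulate", {
    if (!is.null(cfg$data_dir)) {
      if (!dir.exists(cfg$data_dir)) {
        stop(sprintf("input path does not exist: %s", cfg$data_dir))
      }
      dirs <- list.dirs(cfg$data_dir, recursive = FALSE)
      if (length(dirs) < 3) stop("need at least 3 sequence directories")
      setNames(lapply(dirs, read_experiment), basename(dirs))
    } else {
      setNames(
        lapply(seq_len(cfg$n_sequences), function(i) {
          sc <- cfg$sim
          sc$seed <- seeds$sim[i]
          simulate_experiment(sc, cfg$optics)
        }),
        sprintf("seq%02d", seq_len(cfg$n_sequences))
      )
    }
  })

  phases <- stage_run("reconstruct", {
    lapply(experiments, function(ex)
      lapply(ex$stacks, reconstruct_phase, cfg = cfg$optics))
  })

  gt_maps <- stage_run("make-gt", {
    lapply(experiments, function(ex)
      lapply(ex$fluors, make_semantic_map, cfg = cfg$gt))
  })

  split <- stage_run("split", {
    split_sequences(names(experiments), seed = seeds$split)
  })

  frames <- stage_run("assemble", {
    dplyr::bind_rows(purrr::imap(experiments, function(ex, nm) {
      tibble::tibble(
        sequence_id = nm,
        frame = seq_along(phases[[nm]]),
        image = lapply(phases[[nm]], function(p) p$phase),
        labels = gt_maps[[nm]]
      )
    }))
  })

  tcfg <- cfg$train
  tcfg$seed <- seeds$train
  model <- stage_run("train", {
    train_segmenter(NULL, frames, split, tcfg)
  })

  test_frames <- frames[frames$sequence_id %in% split$test, ]
  preds <- stage_run("predict", {
    lapply(test_frames$image, function(img) predict(model, img)$labels)
  })

  eval_res <- stage_run("evaluate", {
    counts <- matrix(0L, 2, 2, dimnames = list(pred = c("live", "dead"),
                                               gt = c("live", "dead")))
    missed <- c(live = 0L, dead = 0L)
    for (i in seq_along(preds)) {
      cm <- object_confusion(test_frames$labels[[i]], preds[[i]],
                             min_area_px = cfg$gt$min_area_px)
      counts <- counts + cm$counts
      missed <- missed + cm$missed
    }
    total <- structure(list(counts = counts, n_live = sum(counts[, "live"]),
                            n_dead = sum(counts[, "dead"]), missed = missed),
                       class = "viab_confusion")
    list(confusion = total,
         normalized = if (total$n_live > 0 && total$n_dead > 0)
           normalize_confusion(total) else NULL,
         prf1 = if (total$n_live > 0 && total$n_dead > 0) prf1(total) else NULL)
  })

  track_res <- stage_run("track", {
    lapply(split$test, function(sid) {
      pos <- which(test_frames$sequence_id == sid)
      maps <- preds[pos]
      tr <- tryCatch(
        link_tracks(maps, max_disp_px = cfg$max_disp_px,
                    min_len = min(cfg$min_len, length(maps)),
                    min_area_px = cfg$gt$min_area_px),
        error = function(e) NULL
      )
      if (is.null(tr) || nrow(tr) == 0) return(NULL)
      measure_track(tr, phases[[sid]], cfg$optics)
    })
  })
  tracks <- dplyr::bind_rows(track_res)

  report <- list(
    seeds = seeds,
    n_sequences = length(experiments),
    split = split,
    history = model$history,
    confusion_counts = eval_res$confusion$counts,
    missed = eval_res$confusion$missed,
    normalized_confusion = eval_res$normalized,
    prf1 = eval_res$prf1,
    macro_f1_pct = if (!is.null(eval_res$prf1))
      eval_res$prf1$f1_pct[eval_res$prf1$class == "macro"] else NA_real_,
    n_tracks = if (nrow(tracks)) length(unique(tracks$track_id)) else 0L
  )

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    stage_run("write-report", {
      write_report_json(report, file.path(cfg$out_dir, "report.json"))
      readr::write_csv(model$history, file.path(cfg$out_dir, "history.csv"))
      save_weights(model, file.path(cfg$out_dir, "weights.rds"))
      if (nrow(tracks)) {
        write_tracks_csv(tracks, file.path(cfg$out_dir, "tracks.csv"))
      }
    })
  }
  report$model <- model
  report$tracks <- tracks
  report
}
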