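# End-to-end seeded experiments: phantom cohort -> training pipeline(s) ->
# prediction -> evaluation report, all materialized in a self-describing
# artifact directory (resolved config + seed suffice to regenerate it).

#' Experiment configuration
#'
#' @param task `"mid-rt"` (single-stage pipelines on the mid timepoint,
#'   variants among `c1`, `c3`, `staged_c3`) or `"pre-rt"` (two-stage
#'   pipelines on the pre timepoint, variants among `baseline`, `c1`, `c2`).
#' @param variants character vector of pipeline variants to train and
#'   compare.
#' @param n_cases cohort size; the first `ceiling(split * n_cases)` cases
#'   train, the rest validate.
#' @param split training fraction.
#' @param phantom a [phantom_params()] object.
#' @param stage a [stage_config()] template applied to every variant (the
#'   pipeline forces recipe/sampler per variant).
#' @param seed master seed: cohort generation and each stage derive their
#'   seeds from it.
#' @param preset `"desk-smoke"` (a couple of minutes: tiny cohort, short
#'   schedule), `"desk-study"` (minutes: the 20-case study layout with a
#'   ~600-step schedule), or `"full-scale"` (the reference schedule —
#'   1000 epochs of 250 steps, batch 2, patch 320 x 256 x 64, momentum
#'   0.99 — expressible for completeness but far beyond desk runtimes);
#'   `NULL` keeps the explicit arguments.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(task = c("mid-rt", "pre-rt"),
                              variants = c("c1", "staged_c3"),
                              n_cases = 20L, split = 0.8,
                              phantom = phantom_params(),
                              stage = stage_config(),
                              seed = 1L, preset = NULL) {
  task <- match.arg(task)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk-smoke", "desk-study", "full-scale"))
    if (preset == "full-scale") {
      n_cases <- 150L
      split <- 0.8
      stage <- stage_config(patch_size = c(320L, 256L, 64L), batch_size = 2L,
                            epochs = 1000L, steps_per_epoch = 250L,
                            momentum = 0.99,
                            net = net_config(n_stages = 6L, base_channels = 32L),
                            seed = stage$seed)
    } else if (preset == "desk-smoke") {
      n_cases <- 4L
      stage <- stage_config(patch_size = c(16L, 16L, 16L), batch_size = 2L,
                            epochs = 2L, steps_per_epoch = 5L, momentum = 0.9,
                            net = net_config(n_stages = 2L, base_channels = 4L,
                                             ds_levels = 1L),
                            seed = stage$seed)
      phantom <- phantom_params(shape = c(32L, 32L, 16L),
                                gtvp_radius_range = c(4, 6),
                                gtvn_radius_range = c(2.5, 3.5))
    } else {
      n_cases <- 20L
      stage <- stage_config(patch_size = c(32L, 32L, 32L), batch_size = 2L,
                            epochs = 15L, steps_per_epoch = 40L,
                            momentum = 0.9, val_patches_per_case = 1L,
                            net = net_config(n_stages = 3L, base_channels = 3L),
                            seed = stage$seed)
    }
  }
  valid <- if (task == "mid-rt") c("c1", "c3", "staged_c3")
           else c("baseline", "c1", "c2")
  bad <- setdiff(variants, valid)
  if (length(bad))
    stopf("experiment_config: invalid %s variants: %s", task,
          paste(bad, collapse = ", "))
  structure(list(task = task, variants = variants,
                 n_cases = as.integer(n_cases), split = split,
                 phantom = phantom, stage = stage, seed = as.integer(seed)),
            class = "experiment_config")
}

config_as_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

#' Run a seeded end-to-end experiment
#'
#' Generates the phantom cohort, trains every configured variant, runs
#' inference on the validation cases, evaluates, and writes an artifact
#' directory: `config.json`, per-variant `history_<v>.csv` and prediction
#' NIfTIs, and the `report/` CSV tables.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir artifact directory; refuses a non-empty existing directory
#'   unless `resume = TRUE`.
#' @param resume allow writing into a non-empty directory.
#' @param write_volumes also write the cohort and predictions as NIfTI
#'   (default FALSE to keep smoke runs light).
#' @return list with `results` (per-variant `eval_result`s), `report`,
#'   `pipelines` (per-variant pipeline outputs), and `out_dir`.
#' @export
run_experiment <- function(cfg, out_dir, resume = FALSE,
                           write_volumes = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !resume)
    stopf("run_experiment: '%s' is not empty; pass resume = TRUE to reuse it",
          out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_cohort(cfg$phantom, cfg$n_cases, seed = cfg$seed)
  tp <- if (cfg$task == "mid-rt") "mid" else "pre"
  cases <- lapply(cohort, `[[`, tp)
  n_train <- max(1L, min(cfg$n_cases - 1L, ceiling(cfg$split * cfg$n_cases)))
  train_cases <- cases[seq_len(n_train)]
  val_cases <- cases[(n_train + 1L):cfg$n_cases]
  results <- list(); pipelines <- list()
  for (v in cfg$variants) {
    st <- cfg$stage
    st$seed <- as.integer(derive_seed(cfg$seed, match(v, cfg$variants)))
    pl <- if (cfg$task == "mid-rt") {
      run_mid_rt_pipeline(v, train_cases, val_cases, st)
    } else {
      cfg2 <- st
      cfg2$sampler <- "masked"; cfg2$prior_source <- "stage1_output"
      cfg2$seed <- as.integer(derive_seed(st$seed, 2L))
      run_pre_rt_pipeline(v, train_cases, val_cases, cfg1 = st, cfg2 = cfg2)
    }
    pipelines[[v]] <- pl
    pairs <- lapply(val_cases, function(vc)
      list(pred = pl$predictions[[vc$case_id]], ref = vc$reference))
    names(pairs) <- vapply(val_cases, `[[`, "", "case_id")
    results[[v]] <- evaluate_pairs(pairs)
    hist <- if (cfg$task == "mid-rt") pl$stage$history else pl$stage1$history
    write.csv(hist, file.path(out_dir, sprintf("history_%s.csv", v)),
              row.names = FALSE)
    if (write_volumes) {
      pd <- file.path(out_dir, "predictions", v)
      dir.create(pd, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(pl$predictions))
        write_labelmap(pl$predictions[[nm]],
                       file.path(pd, paste0(nm, ".nii.gz")))
    }
  }
  best_epochs <- vapply(pipelines, function(pl) {
    st <- if (cfg$task == "mid-rt") pl$stage else pl$stage2 %||% pl$stage1
    as.integer(st$best_epoch)
  }, 1L)
  report <- eval_report(results, out_dir = file.path(out_dir, "report"),
                        best_epochs = best_epochs)
  jsonlite::write_json(config_as_list(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (write_volumes) {
    cd <- file.path(out_dir, "cohort")
    for (pair in cohort) {
      write_case(pair$pre, cd)
      write_case(pair$mid, cd)
    }
  }
  list(results = results, report = report, pipelines = pipelines,
       out_dir = out_dir)
}
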