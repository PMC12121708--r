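#' Write a pattern dataset to disk
#'
#' Two on-disk encodings are supported:
#' \describe{
#'   \item{`"nifti"`}{one NIfTI volume per (run, condition) plus
#'     `mask.nii.gz` and a `manifest.json` sidecar recording the grid,
#'     labels, runs and file names.}
#'   \item{`"tsv"`}{a single flat table `dataset.tsv` (columns `i`, `j`,
#'     `k`, then one `run<r>.<condition>` column per cell) plus
#'     `dataset.json` with the grid and labels — a diff-able format for
#'     headless tests.}
#' }
#'
#' @param dataset A [pattern_dataset].
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_pattern_dataset <- function(dataset, dir, format = c("nifti", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "pattern_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- dataset$grid
  meta <- list(format = format, dims = grid$dims,
               voxel_size_mm = grid$voxel_size_mm, origin = grid$origin,
               condition_labels = dataset$condition_labels,
               n_runs = dataset$n_runs, provenance = dataset$provenance)
  if (format == "nifti") {
    vol_of <- function(values) {
      v <- array(NA_real_, grid$dims)
      v[dataset$mask_index] <- values
      v
    }
    files <- list()
    for (r in seq_len(dataset$n_runs)) for (cond in dataset$condition_labels) {
      fn <- sprintf("pattern_run%d_%s.nii.gz", r, cond)
      RNifti::writeNifti(
        RNifti::asNifti(vol_of(dataset$patterns[, r, cond]),
                        pixdim = grid$voxel_size_mm),
        file.path(dir, fn))
      files[[length(files) + 1]] <- list(run = r, condition = cond, file = fn)
    }
    RNifti::writeNifti(
      RNifti::asNifti(array(as.numeric(dataset$mask), grid$dims),
                      pixdim = grid$voxel_size_mm),
      file.path(dir, "mask.nii.gz"))
    meta$mask_file <- "mask.nii.gz"
    meta$files <- files
    jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    ijk <- arrayInd(dataset$mask_index, grid$dims)
    tab <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3])
    for (r in seq_len(dataset$n_runs)) for (cond in dataset$condition_labels)
      tab[[sprintf("run%d.%s", r, cond)]] <- dataset$patterns[, r, cond]
    utils::write.table(tab, file.path(dir, "dataset.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a pattern dataset from disk
#'
#' Reads either encoding written by [write_pattern_dataset()], validating
#' grid consistency across volumes, completeness of the (run, condition)
#' grid, and absence of non-finite values inside the mask.
#'
#' @param path Directory containing `manifest.json` or `dataset.tsv`.
#' @return A [pattern_dataset].
#' @export
read_pattern_dataset <- function(path) {
  if (file.exists(file.path(path, "manifest.json")))
    return(read_dataset_nifti(path))
  if (file.exists(file.path(path, "dataset.tsv")))
    return(read_dataset_tsv(path))
  stop("no manifest.json or dataset.tsv found in ", path)
}

dataset_meta <- function(meta) {
  volume_grid(unlist(meta$dims), unlist(meta$voxel_size_mm),
              unlist(meta$origin))
}

check_complete <- function(found, n_runs, condition_labels) {
  want <- as.vector(outer(seq_len(n_runs), condition_labels,
                          function(r, cond) paste(r, cond)))
  missing <- setdiff(want, found)
  if (length(missing))
    stop("dataset is missing (run, condition) cell(s): ",
         paste(missing, collapse = "; "))
}

read_dataset_nifti <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "manifest.json"))
  grid <- dataset_meta(meta)
  labels <- unlist(meta$condition_labels)
  n_runs <- meta$n_runs
  mask_arr <- array(as.vector(RNifti::readNifti(
    file.path(path, meta$mask_file))), grid$dims)
  mask <- mask_arr != 0
  if (!any(mask)) stop("mask is empty")
  mask_index <- which(mask)
  found <- vapply(meta$files, function(f) paste(f$run, f$condition),
                  character(1))
  check_complete(found, n_runs, labels)
  pats <- array(0, c(length(mask_index), n_runs, length(labels)),
                dimnames = list(NULL, NULL, labels))
  for (f in meta$files) {
    v <- RNifti::readNifti(file.path(path, f$file))
    if (!identical(dim(v)[1:3], grid$dims))
      stop(sprintf("grid mismatch in %s: %s vs %s", f$file,
                   paste(dim(v), collapse = "x"),
                   paste(grid$dims, collapse = "x")))
    vals <- array(as.vector(v), grid$dims)[mask_index]
    if (any(!is.finite(vals)))
      stop(sprintf("non-finite voxel(s) inside the mask in %s", f$file))
    pats[, f$run, f$condition] <- vals
  }
  structure(list(grid = grid, mask = mask, mask_index = mask_index,
                 patterns = pats, condition_labels = labels,
                 n_runs = n_runs,
                 provenance = sprintf("read from %s", path)),
            class = "pattern_dataset")
}

read_dataset_tsv <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "dataset.json"))
  grid <- dataset_meta(meta)
  labels <- unlist(meta$condition_labels)
  n_runs <- meta$n_runs
  tab <- utils::read.delim(file.path(path, "dataset.tsv"),
                           check.names = FALSE)
  mask_index <- tab$i + (tab$j - 1) * grid$dims[1] +
    (tab$k - 1) * grid$dims[1] * grid$dims[2]
  mask <- array(FALSE, grid$dims)
  mask[mask_index] <- TRUE
  cols <- setdiff(names(tab), c("i", "j", "k"))
  parsed <- regmatches(cols, regexec("^run([0-9]+)\\.(.+)$", cols))
  found <- vapply(parsed, function(p) paste(p[2], p[3]), character(1))
  check_complete(found, n_runs, labels)
  pats <- array(0, c(nrow(tab), n_runs, length(labels)),
                dimnames = list(NULL, NULL, labels))
  for (ci in seq_along(cols)) {
    vals <- tab[[cols[ci]]]
    if (any(!is.finite(vals)))
      stop(sprintf("non-finite voxel(s) inside the mask in column %s",
                   cols[ci]))
    pats[, as.integer(parsed[[ci]][2]), parsed[[ci]][3]] <- vals
  }
  structure(list(grid = grid, mask = mask, mask_index = mask_index,
                 patterns = pats, condition_labels = labels,
                 n_runs = n_runs,
                 provenance = sprintf("read from %s", path)),
            class = "pattern_dataset")
}

# ---- pipeline configuration -------------------------------------------------

pipeline_defaults <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    dataset_dir = NULL,
    simulate = list(n_subjects = 3, grid_dims = c(10, 10, 10),
                    voxel_size_mm = c(3, 3, 3), n_runs = 5),
    rsa = list(enabled = TRUE,
               models = c("self_other", "self_introspection", "self_memory")),
    mvpa = list(enabled = TRUE, cost = 1, center = FALSE),
    regvpa = list(enabled = TRUE, ceiling = TRUE, vpa = TRUE),
    permnull = list(enabled = FALSE, n_perm = 200, sd_grid_max = 2,
                    sd_grid_step = 0.02, n_rep = 20)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Read and validate a pipeline configuration
#'
#' Loads a JSON configuration, fills defaults, and rejects unknown keys
#' (so typos never silently fall back to defaults). Every random stage
#' derives its seed from the single top-level `seed`.
#'
#' @param path JSON file, or a named list already in memory.
#' @return Validated configuration list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else path
  cfg <- merge_config(pipeline_defaults(), user)
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages: simulate (or load) per-subject pattern
#' datasets, ROI-level RSA model fits (Kendall tau-a for each model RSM),
#' classifier discriminability for the three standard contrast pairs,
#' cross-run pattern regression with noise ceiling, variance partitioning,
#' and optionally the smoothness-matched permutation null on the first
#' subject. Writes TSV result tables and a JSON run record (parameters,
#' seeds, package version) to the output directory; reruns with the same
#' configuration are byte-identical.
#'
#' @param config A configuration (path, list, or [read_run_config()]
#'   output).
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  datasets <- stage("data", {
    if (!is.null(cfg$dataset_dir)) {
      list(read_pattern_dataset(cfg$dataset_dir))
    } else {
      sim <- cfg$simulate
      grid <- volume_grid(sim$grid_dims, sim$voxel_size_mm)
      lapply(seq_len(sim$n_subjects), function(s)
        generate_pattern_dataset(planted_vpa_spec(
          grid, n_runs = sim$n_runs, seed = cfg$seed * 1000 + s)))
    }
  })
  n_sub <- length(datasets)
  if (isTRUE(cfg$rsa$enabled)) stage("rsa", {
    rows <- list()
    for (s in seq_len(n_sub)) {
      ds <- datasets[[s]]
      nr <- build_neural_rsm(ds)
      for (m in cfg$rsa$models) {
        mr <- build_model_rsm(m, ds$n_runs, ds$condition_labels)
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, model = m, tau_a = kendall_tau_a(nr, mr))
      }
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "rsa.tsv"))
  })
  if (isTRUE(cfg$mvpa$enabled)) stage("mvpa", {
    dc <- default_contrasts()
    pairs <- list(
      self_vs_other = c("self_gt_semantic", "other_gt_semantic"),
      self_vs_introspection = c("self_gt_semantic",
                                "introspection_gt_categorization"),
      self_vs_memory = c("self_gt_semantic", "memory_gt_knowledge"))
    rows <- list()
    for (s in seq_len(n_sub)) {
      ds <- datasets[[s]]
      for (pn in names(pairs)) {
        cv <- loro_cv_accuracy(compute_contrast(ds, dc[[pairs[[pn]][1]]]),
                               compute_contrast(ds, dc[[pairs[[pn]][2]]]),
                               cost = cfg$mvpa$cost,
                               center = cfg$mvpa$center)
        rows[[length(rows) + 1]] <- data.frame(
          subject = s, comparison = pn, accuracy = cv$mean_accuracy)
      }
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "mvpa.tsv"))
  })
  if (isTRUE(cfg$regvpa$enabled)) stage("regvpa", {
    rows <- list()
    vrows <- list()
    for (s in seq_len(n_sub)) {
      ds <- datasets[[s]]
      full <- fit_runpair_regressions(ds)
      row <- data.frame(subject = s, t(full$mean_betas),
                        r2 = full$mean_r2, adj_r2 = full$mean_adj_r2)
      if (isTRUE(cfg$regvpa$ceiling))
        row$ceiling_adj_r2 <- fit_noise_ceiling(ds)$mean_adj_r2
      rows[[s]] <- row
      if (isTRUE(cfg$regvpa$vpa)) {
        vp <- variance_partition(ds)
        vrows[[s]] <- data.frame(subject = s, t(vp$portions),
                                 full_r2 = vp$full_r2,
                                 full_adj_r2 = vp$full_adj_r2)
      }
    }
    reg <- do.call(rbind, rows)
    write_tsv(reg, file.path(out_dir, "regvpa.tsv"))
    if (length(vrows))
      write_tsv(do.call(rbind, vrows), file.path(out_dir, "vpa.tsv"))
    if (isTRUE(cfg$regvpa$ceiling)) {
      pct <- explainable_variance_pct(reg$adj_r2, reg$ceiling_adj_r2)
      write_tsv(data.frame(explainable_variance_pct = pct),
                file.path(out_dir, "explainable_variance.tsv"))
    }
  })
  if (isTRUE(cfg$permnull$enabled)) stage("permnull", {
    ds <- datasets[[1]]
    roi_index <- ds$mask_index
    self_runs <- matrix(ds$patterns[, , "self"], ncol = ds$n_runs)
    control_runs <- matrix(ds$patterns[, , "semantic"], ncol = ds$n_runs)
    W <- morans_weights(voxel_coords_mm(ds$grid, roi_index))
    calib <- calibrate_smoothing_sd(
      rowMeans(self_runs), roi_index, ds$grid$dims, W,
      sd_grid = seq(0, cfg$permnull$sd_grid_max,
                    by = cfg$permnull$sd_grid_step),
      n_rep = cfg$permnull$n_rep, seed = cfg$seed + 77)
    write_tsv(data.frame(sd = calib$sd_grid, sse = calib$sse),
              file.path(out_dir, "permnull_calibration.tsv"))
    Xl <- lapply(default_vpa_predictors(), function(sp)
      compute_contrast(ds, sp)$per_run)
    pn <- permuted_statistic_null(
      self_runs, control_runs, roi_index, ds$grid$dims, calib,
      runpair_statistic(Xl, portions = TRUE),
      n_perm = cfg$permnull$n_perm, seed = cfg$seed + 78)
    write_tsv(data.frame(statistic = names(pn$observed),
                         observed = as.numeric(pn$observed),
                         p = as.numeric(pn$p_values)),
              file.path(out_dir, "permnull.tsv"))
  })
  record <- list(package_version = as.character(utils::packageVersion("mvpatterns")),
                 config = unclass(cfg), n_subjects = n_sub)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
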