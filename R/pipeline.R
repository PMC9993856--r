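#' Two-arm experiment configuration
#'
#' Describes a phantom cohort experiment comparing (arm A) direct
#' registration of the planning CT to the degraded CBCT with (arm B)
#' registration to the translated synthetic CT, with identical demons
#' settings in both arms.
#'
#' @param n_cases number of evaluation cases.
#' @param seed cohort master seed; per-case seeds are derived from it.
#' @param phantom a [phantom_config()] (per-case texture seeds vary).
#' @param artifact an [artifact_config()].
#' @param deformation list with `amplitude_mm`, `smoothness_mm` for the
#'   ground-truth inter-fraction deformation.
#' @param demons a [demons_config()].
#' @param generator a [generator_spec()].
#' @param loss a [loss_config()].
#' @param train a [train_config()]; used when no pretrained `model` is given.
#' @param n_train_slices training slices generated when training is needed
#'   (split off with seeds disjoint from the evaluation cases).
#' @param model optional pretrained `ClgGenerator`; skips training.
#' @param output_dir optional directory for CSV/NIfTI artifacts.
#' @return an `ExperimentConfig`.
#' @export
experiment_config <- function(n_cases = 20L, seed = 1L,
                              phantom = phantom_config(),
                              artifact = artifact_config(),
                              deformation = list(amplitude_mm = 3,
                                                 smoothness_mm = 20),
                              demons = demons_config(),
                              generator = generator_spec(),
                              loss = loss_config(),
                              train = train_config(epochs = 6L,
                                                   warm_epochs = 2L),
                              n_train_slices = 40L,
                              model = NULL, output_dir = NULL) {
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 phantom = phantom, artifact = artifact,
                 deformation = deformation, demons = demons,
                 generator = generator, loss = loss, train = train,
                 n_train_slices = as.integer(n_train_slices),
                 model = model, output_dir = output_dir),
            class = "ExperimentConfig")
}

#' Generate one synthetic patient case
#'
#' Builds the planning image with its contours, a ground-truth smooth
#' deformation standing in for inter-fraction anatomical change, the
#' deformed fraction anatomy, its CBCT-style degradation, and the reference
#' contours (the planning contours carried through the ground-truth
#' deformation, standing in for physician delineation on the fraction
#' image).
#'
#' @param phantom a [phantom_config()].
#' @param artifact an [artifact_config()].
#' @param deformation list with `amplitude_mm` and `smoothness_mm`.
#' @param seed case seed.
#' @return list with `pct`, `pct_structures`, `cbct`, `fraction`,
#'   `reference_structures`, `dvf_gt`.
#' @export
make_phantom_case <- function(phantom = phantom_config(),
                              artifact = artifact_config(),
                              deformation = list(amplitude_mm = 3,
                                                 smoothness_mm = 20),
                              seed = 1L) {
  pcfg <- phantom; pcfg$seed <- as.integer(seed)
  ph <- generate_phantom(pcfg)
  dvf_gt <- sample_smooth_deformation(dim(ph$image$values), ph$image$spacing,
                                      deformation$amplitude_mm,
                                      deformation$smoothness_mm,
                                      seed = seed + 1000L)
  fraction <- warp_image(ph$image, dvf_gt, "linear")
  ref <- warp_structures(ph$structures, dvf_gt)
  acfg <- artifact; acfg$seed <- as.integer(seed + 2000L)
  cbct <- degrade_to_cbct(fraction, acfg)
  list(pct = ph$image, pct_structures = ph$structures, cbct = cbct,
       fraction = fraction, reference_structures = ref, dvf_gt = dvf_gt)
}

#' Run the two-arm registration experiment on one case
#'
#' Arm A registers the planning CT to the CBCT directly; arm B first
#' translates the CBCT to a synthetic CT and registers to that.  Both arms
#' share the same `demons_config` (the fixed image is the only difference —
#' asserted programmatically), propagate the planning contours with their
#' DVF using nearest-neighbour warping, and are scored against the
#' reference contours.
#'
#' @param pct planning `ImageGrid` (moving image in both arms).
#' @param cbct degraded fraction `ImageGrid` (fixed image, arm A).
#' @param pct_contours `StructureSet` on the planning image.
#' @param reference_contours `StructureSet` on the fraction anatomy.
#' @param model a `ClgGenerator` (arm B translation).
#' @param demons_cfg a [demons_config()].
#' @return list with `armA`, `armB` (each: `dvf`, `warped`, `structures`,
#'   `metrics`, `fixed_config_hash`) and `sct`.
#' @export
run_case <- function(pct, cbct, pct_contours, reference_contours, model,
                     demons_cfg = demons_config()) {
  sct <- translate(cbct, model)
  run_arm <- function(fixed) {
    reg <- register_diffeodemons(fixed, pct, demons_cfg)
    warped <- warp_image(pct, reg$dvf, "linear")
    prop <- warp_structures(pct_contours, reg$dvf)
    list(dvf = reg$dvf, warped = warped, structures = prop,
         metrics = evaluate_structures(prop, reference_contours),
         diagnostics = reg$diagnostics,
         config_hash = config_hash(demons_cfg))
  }
  armA <- run_arm(cbct)
  armB <- run_arm(sct)
  stopifnot(identical(armA$config_hash, armB$config_hash))
  list(armA = armA, armB = armB, sct = sct)
}

config_hash <- function(cfg) {
  paste(deparse(cfg[order(names(cfg))], control = "all"), collapse = "")
}

#' Run a full phantom cohort through both registration arms
#'
#' Trains the translation model if no pretrained one is supplied (training
#' slices use seeds disjoint from the evaluation cases), generates
#' `n_cases` deformed, degraded cases, runs [run_case()] on each (a failed
#' case is recorded with its stage diagnostics and the cohort continues;
#' more than 50% failures marks the whole cohort failed), and aggregates
#' per-structure metrics per arm.  With `output_dir` set, writes per-case
#' and summary CSVs plus NIfTI volumes and DVFs.  Fully reproducible from
#' the config seeds.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress.
#' @return list with `per_case` (long data.frame), `summary` (per-arm
#'   aggregates), `model`, `failed_cases`, `status`.
#' @export
run_cohort <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  model <- config$model
  if (is.null(model)) {
    tr <- cohort_training_images(config)
    fit <- train_clg(tr$x, tr$y, config$generator, config$loss, config$train)
    model <- fit$model
  }
  per_case <- list()
  failed <- integer(0)
  for (i in seq_len(config$n_cases)) {
    case_seed <- config$seed + 10L * i
    res <- tryCatch({
      cs <- make_phantom_case(config$phantom, config$artifact,
                              config$deformation, seed = case_seed)
      rc <- run_case(cs$pct, cs$cbct, cs$pct_structures,
                     cs$reference_structures, model, config$demons)
      if (!is.null(config$output_dir)) write_case_artifacts(config, i, cs, rc)
      rc
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("case ", i, " failed: ", conditionMessage(res))
      failed <- c(failed, i)
      next
    }
    for (arm in c("armA", "armB")) {
      m <- as.data.frame(res[[arm]]$metrics)
      m$case <- i
      m$arm <- if (arm == "armA") "pCT-CBCT" else "pCT-sCT"
      per_case[[length(per_case) + 1]] <- m
    }
    if (verbose) message("case ", i, " done")
  }
  status <- if (length(failed) > config$n_cases / 2) "failed" else "ok"
  long <- if (length(per_case)) do.call(rbind, per_case) else NULL
  summary <- NULL
  if (!is.null(long)) {
    summary <- do.call(rbind, lapply(split(long, long$arm), function(sub) {
      reports <- lapply(split(sub, sub$case), function(r)
        r[, c("structure", "DSC", "HD95_mm", "ASD_mm")])
      agg <- aggregate_metrics(unname(reports))
      agg$arm <- sub$arm[1]
      agg
    }))
    rownames(summary) <- NULL
  }
  if (!is.null(config$output_dir) && !is.null(long)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(long, file.path(config$output_dir, "per_case.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(per_case = long, summary = summary, model = model,
       failed_cases = failed, status = status)
}

## training images: degraded slices (x) and clean slices (y), seeds disjoint
## from evaluation cases (which use seed + 10*i, i >= 1)
cohort_training_images <- function(config) {
  n <- config$n_train_slices
  xs <- vector("list", n); ys <- vector("list", n)
  for (j in seq_len(n)) {
    seed_j <- config$seed + 100000L + 7L * j
    pcfg <- config$phantom; pcfg$seed <- seed_j
    ph <- generate_phantom(pcfg)
    dv <- sample_smooth_deformation(dim(ph$image$values), ph$image$spacing,
                                    config$deformation$amplitude_mm,
                                    config$deformation$smoothness_mm,
                                    seed = seed_j + 1L)
    frac <- warp_image(ph$image, dv, "linear")
    acfg <- config$artifact; acfg$seed <- seed_j + 2L
    xs[[j]] <- degrade_to_cbct(frac, acfg)
    # unpaired target-domain slice: a different clean phantom
    pcfg2 <- config$phantom; pcfg2$seed <- seed_j + 500000L
    ys[[j]] <- generate_phantom(pcfg2)$image
  }
  list(x = xs, y = ys)
}

write_case_artifacts <- function(config, i, cs, rc) {
  d <- file.path(config$output_dir, sprintf("case%03d", i))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_volume(cs$pct, file.path(d, "pct.nii"))
  write_volume(cs$cbct, file.path(d, "cbct.nii"))
  write_volume(rc$sct, file.path(d, "sct.nii"))
  write_dvf(rc$armA$dvf, file.path(d, "dvf_pct_cbct.nii"))
  write_dvf(rc$armB$dvf, file.path(d, "dvf_pct_sct.nii"))
  write_structures(cs$reference_structures, file.path(d, "ref"))
  write_structures(rc$armA$structures, file.path(d, "propA"))
  write_structures(rc$armB$structures, file.path(d, "propB"))
  utils::write.csv(rc$armA$diagnostics, file.path(d, "energy_armA.csv"),
                   row.names = FALSE)
  utils::write.csv(rc$armB$diagnostics, file.path(d, "energy_armB.csv"),
                   row.names = FALSE)
}

#' Proportional train/validation/test split of case indices
#'
#' Mirrors the 52/7/41 patient split pattern proportionally for a cohort of
#' any size.
#'
#' @param n number of cases.
#' @param proportions split proportions; default `c(52, 7, 41) / 100`.
#' @return list with integer index vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(n, proportions = c(52, 7, 41) / 100) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, n >= 3)
  n_train <- max(1L, round(n * proportions[1]))
  n_val <- max(1L, round(n * proportions[2]))
  if (n_train + n_val >= n) n_train <- n - n_val - 1L
  idx <- seq_len(n)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n])
}
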