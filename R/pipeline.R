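#' Experiment orchestration
#'
#' Runs the full forecasting experiment grid -- thickness-scaling modes x
#' loading schemes x failure thresholds -- over a cohort, producing
#' per-knee degenerated-volume fractions, a Table-style AUC grid for the
#' three KL-group contrasts in the lateral, medial and overall knee, and a
#' manifest recording configuration hash and seeds. Per-knee failures
#' (e.g. a frame exceeding the contact capacity) are logged and skipped,
#' not fatal.
#'
#' @name pipeline
NULL

#' Build a run configuration
#'
#' @param cohort Optional pre-built cohort `data.frame`; when `NULL` a
#'   synthetic cohort of `n` knees is generated.
#' @param n,seed,effect_size Synthetic-cohort parameters (see
#'   [generate_cohort()]). `seed` also derives the predictor-training and
#'   noise seeds.
#' @param thickness_modes Subset of `c("fixed_ratio", "scaled_ratio")`.
#' @param loading_modes Subset of `c("5050", "ls_nn", "ls_peak_nn")`.
#' @param thresholds List of threshold specifications, each
#'   `list(kind = "kempson")` or `list(kind = "weightman", cycles = N)`.
#' @param resolution Template resolution, `list(nx, nz, n_layers)`.
#' @param central_fraction Central-region fraction (default 1/3).
#' @param peak_bw_multiplier Reference-curve peak, body weights.
#' @param contact_fraction Cartilage-contact fraction of compartment JCF.
#' @param n_train Size of the surrogate NN training cohort.
#' @param predictor Optional pre-trained [train_peak_predictor()] model
#'   (reused across replicate runs to save time).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = NULL, n = 97, seed = 1, effect_size = 1.5,
                       thickness_modes = c("fixed_ratio", "scaled_ratio"),
                       loading_modes = c("5050", "ls_nn", "ls_peak_nn"),
                       thresholds = list(
                         list(kind = "kempson"),
                         list(kind = "weightman", cycles = 1e5),
                         list(kind = "weightman", cycles = 1e6),
                         list(kind = "weightman", cycles = 1e7)),
                       resolution = list(nx = 12, nz = 8, n_layers = 3),
                       central_fraction = 1 / 3,
                       peak_bw_multiplier = 2.6,
                       contact_fraction = 1,
                       n_train = 500, predictor = NULL, out_dir = NULL) {
  stopifnot(length(thickness_modes) >= 1, length(loading_modes) >= 1,
            length(thresholds) >= 1)
  thickness_modes <- match.arg(thickness_modes,
                               c("fixed_ratio", "scaled_ratio"),
                               several.ok = TRUE)
  loading_modes <- match.arg(loading_modes,
                             c("5050", "ls_nn", "ls_peak_nn"),
                             several.ok = TRUE)
  structure(list(cohort = cohort, n = n, seed = seed,
                 effect_size = effect_size,
                 thickness_modes = thickness_modes,
                 loading_modes = loading_modes, thresholds = thresholds,
                 resolution = resolution,
                 central_fraction = central_fraction,
                 peak_bw_multiplier = peak_bw_multiplier,
                 contact_fraction = contact_fraction,
                 n_train = n_train, predictor = predictor,
                 out_dir = out_dir),
            class = "run_config")
}

.threshold_label <- function(thr) {
  if (thr$kind == "kempson") "kempson"
  else sprintf("weightman_1e%d", as.integer(round(log10(thr$cycles))))
}

.threshold_value <- function(thr, age) {
  if (thr$kind == "kempson") threshold_kempson(age)
  else threshold_weightman(age, thr$cycles)
}

#' Run the experiment grid
#'
#' @param config A [run_config()].
#' @return List with `results` (one row per knee x variant x threshold),
#'   `auc_grid` (AUC and DeLong p per variant x threshold x compartment
#'   scope x KL contrast), `cohort`, `failures`, the trained `predictor`,
#'   and a deterministic `manifest`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (is.null(config$cohort)) {
    generate_cohort(config$n, config$seed, config$effect_size)
  } else {
    validate_cohort(config$cohort)
    config$cohort
  }
  res <- config$resolution
  templates <- list(
    medial = build_template("medial", res$nx, res$nz, res$n_layers,
                            central_fraction = config$central_fraction),
    lateral = build_template("lateral", res$nx, res$nz, res$n_layers,
                             central_fraction = config$central_fraction))
  curve <- reference_curve(config$peak_bw_multiplier)
  props <- default_props()

  predictor <- config$predictor
  if (is.null(predictor) && any(config$loading_modes != "5050")) {
    train_cohort <- generate_cohort(config$n_train, config$seed + 200000L,
                                    effect_size = 0)
    training <- make_training_table(train_cohort, config$seed + 100000L)
    predictor <- train_peak_predictor(training, seed = config$seed + 300000L)
  }

  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(cohort))) {
    subject <- cohort[i, ]
    meas <- cohort_measurements(subject)
    for (tmode in config$thickness_modes) {
      meshes <- lapply(templates, scale_mesh, subject_meas = meas,
                       mode = tmode)
      for (lmode in config$loading_modes) {
        variant <- sprintf("%s|%s", lmode, tmode)
        out <- tryCatch({
          loading <- switch(lmode,
            "5050" = loading_5050(subject, curve, config$contact_fraction),
            "ls_nn" = loading_ls_nn(subject, curve, predictor,
                                    config$contact_fraction),
            "ls_peak_nn" = loading_ls_peak_nn(subject, curve, predictor,
                                              config$contact_fraction))
          fields <- lapply(meshes, simulate_stance, loading = loading,
                           props = props)
          lapply(config$thresholds, function(thr) {
            value <- .threshold_value(thr, subject$age)
            med <- degenerated_volume(fields$medial, meshes$medial, value)
            lat <- degenerated_volume(fields$lateral, meshes$lateral, value)
            knee <- knee_degeneration(med, lat)
            data.frame(
              id = subject$id, kl_group = subject$kl_group,
              age = subject$age, loading_mode = lmode,
              thickness_mode = tmode, variant = variant,
              threshold = .threshold_label(thr), threshold_mpa = value,
              fraction_medial = knee$fraction_medial,
              fraction_lateral = knee$fraction_lateral,
              fraction_overall = knee$fraction_overall,
              fraction_medial_femoral = med$fraction_femoral,
              fraction_medial_tibial = med$fraction_tibial,
              fraction_lateral_femoral = lat$fraction_femoral,
              fraction_lateral_tibial = lat$fraction_tibial,
              share_medial = loading$share_medial,
              stringsAsFactors = FALSE)
          })
        }, error = function(e) e)
        if (inherits(out, "error")) {
          failures[[length(failures) + 1]] <- data.frame(
            id = subject$id, variant = variant,
            message = conditionMessage(out), stringsAsFactors = FALSE)
        } else {
          rows <- c(rows, out)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(id = character(), variant = character(),
               message = character())

  auc_grid <- .auc_grid(results)

  manifest <- list(
    config_hash = .object_hash(config[setdiff(names(config),
                                              c("predictor", "out_dir"))]),
    seed = config$seed, n_knees = nrow(cohort),
    n_variants = length(config$thickness_modes) *
      length(config$loading_modes),
    n_thresholds = length(config$thresholds),
    n_results = if (is.null(results)) 0L else nrow(results),
    n_failures = nrow(failures))

  out <- list(results = results, auc_grid = auc_grid, cohort = cohort,
              failures = failures, predictor = predictor,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(config$out_dir, "degeneration.csv"),
              row.names = FALSE)
    write.csv(auc_grid, file.path(config$out_dir, "auc_grid.csv"),
              row.names = FALSE)
    write.csv(failures, file.path(config$out_dir, "failures.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# AUC + DeLong p for each variant x threshold x compartment scope x KL
# contrast; the positive class is always the more severe group
.auc_grid <- function(results) {
  if (is.null(results) || !nrow(results)) return(NULL)
  contrasts <- list(
    KL01vsKL2 = c(neg = "KL01", pos = "KL2"),
    KL01vsKL34 = c(neg = "KL01", pos = "KL34"),
    KL2vsKL34 = c(neg = "KL2", pos = "KL34"))
  scopes <- c(lateral = "fraction_lateral", medial = "fraction_medial",
              overall = "fraction_overall")
  grid <- expand.grid(variant = unique(results$variant),
                      threshold = unique(results$threshold),
                      scope = names(scopes),
                      contrast = names(contrasts),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- results[results$variant == g$variant &
                     results$threshold == g$threshold, ]
    ct <- contrasts[[g$contrast]]
    pos <- sub[sub$kl_group == ct[["pos"]], scopes[[g$scope]]]
    neg <- sub[sub$kl_group == ct[["neg"]], scopes[[g$scope]]]
    if (length(pos) < 2 || length(neg) < 2) {
      return(cbind(g, auc = NA_real_, p_value = NA_real_,
                   n_pos = length(pos), n_neg = length(neg)))
    }
    dl <- delong_test(pos, neg, comparison_label = g$contrast)
    cbind(g, auc = dl$auc, p_value = dl$p_value, n_pos = dl$n_pos,
          n_neg = dl$n_neg)
  })
  do.call(rbind, rows)
}
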