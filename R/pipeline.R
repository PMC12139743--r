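#' Pipeline configuration
#'
#' All analysis constants with their standard defaults: HFB band 110-140 Hz,
#' 50 Hz notch, 400 Hz epoch rate, 0.5 s response bins, lags 0/0.5/1 s, a
#' 20-value penalty grid log-spaced over 10-10000, 5 folds, 5000 shuffles,
#' alpha 0.05. Every value can be overridden.
#'
#' @param seed master seed; determines every stochastic stage.
#' @param band HFB band edges in Hz.
#' @param notch mains frequency in Hz.
#' @param target_fs epoch sampling rate in Hz.
#' @param bin response bin duration in seconds.
#' @param lags design lags in seconds.
#' @param lambda_n,lambda_range penalty grid size and endpoints.
#' @param k_folds cross-validation folds.
#' @param n_perm permutation iterations.
#' @param alpha significance threshold for the weight-analysis inclusion
#'   filter.
#' @param fs_feat feature rate in Hz.
#' @param interest_complex include `interest` in the complex set.
#' @param cohort list of [default_cohort_spec()] arguments (`n_contacts`,
#'   `complex_age_slope`, `music_weight_scale`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, band = c(110, 140), notch = 50,
                            target_fs = 400, bin = 0.5,
                            lags = c(0, 0.5, 1), lambda_n = 20,
                            lambda_range = c(10, 10000), k_folds = 5,
                            n_perm = 5000, alpha = 0.05, fs_feat = 2,
                            interest_complex = FALSE,
                            cohort = list()) {
  cfg <- list(seed = seed, band = band, notch = notch, target_fs = target_fs,
              bin = bin, lags = lags, lambda_n = lambda_n,
              lambda_range = lambda_range, k_folds = k_folds,
              n_perm = n_perm, alpha = alpha, fs_feat = fs_feat,
              interest_complex = interest_complex, cohort = cohort)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  num_pos <- c("target_fs", "bin", "k_folds", "n_perm", "fs_feat")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop_invalid("invalid config field '", f, "': must be a positive number")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop_invalid("invalid config field 'alpha': must lie in (0, 1)")
  if (length(cfg$band) != 2L || cfg$band[1] >= cfg$band[2])
    stop_invalid("invalid config field 'band': need increasing edges")
  known <- setdiff(names(cfg$cohort),
                   c("n_contacts", "complex_age_slope", "music_weight_scale",
                     "seed"))
  if (length(known))
    stop_invalid("invalid config field 'cohort$", known[1L], "'")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop_invalid("unknown config field '", unknown[1L], "' in ", path)
  do.call(pipeline_config, vals)
}

#' Run the full synthetic-cohort analysis
#'
#' Executes simulate -> design -> encode -> stats -> weights on a synthetic
#' cohort and writes, under `out_dir`: `encoding_results.tsv` (one row per
#' participant x area x condition with per-fold and mean accuracy and the
#' penalty used), `group_stats.json` (group t-tests, voice-effect contrast,
#' children's pSTC permutation tests), `weight_age.tsv` (ranked
#' weight-age correlations), `metadata.tsv`, `events.tsv`, and
#' `manifest.json` (stages completed, full config, seed, package version).
#' Rerunning with the same config produces bit-identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param spec optional [cohort_spec()] overriding the default study layout
#'   (useful for reduced runs).
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `encoding`, `stats`, `weight_age`, `lambda`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, spec = NULL) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fset <- emotion_feature_set(interest_complex = config$interest_complex)
  grid <- ridge_lambda_grid(config$lambda_n, config$lambda_range)

  ## stage 1: simulate
  if (is.null(spec)) {
    coh_args <- config$cohort
    coh_args$seed <- coh_args$seed %||% config$seed
    spec <- do.call(default_cohort_spec, coh_args)
  }
  cohort <- generate_cohort(spec, seed = config$seed, lags = config$lags,
                            fs_feat = config$fs_feat, feature_set = fset)
  write_metadata_tsv(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  write_events_tsv(cohort$schedule, file.path(out_dir, "events.tsv"))

  ## stage 2: design — per-condition lagged designs shared by everyone
  conds <- unique(cohort$bins$condition)
  designs <- lapply(conds, function(cond) {
    keep <- cohort$bins$condition == cond
    blocks <- unique(cohort$bins$block_index[keep])
    feats <- cohort$features[as.character(blocks)]
    X <- build_lagged_design(feats, config$lags, config$fs_feat)
    list(X = X, rows = keep)
  })
  names(designs) <- conds

  ## stage 3: encode — one global penalty, then per-dataset evaluation
  datasets <- list()
  keys <- list()
  for (pid in names(cohort$data)) {
    for (area in names(cohort$data[[pid]])) {
      for (cond in conds) {
        d <- designs[[cond]]
        cc <- concatenate_contacts(
          cohort$data[[pid]][[area]][d$rows, , drop = FALSE], d$X)
        datasets[[length(datasets) + 1L]] <- cc
        keys[[length(keys) + 1L]] <- list(id = pid, area = area, cond = cond)
      }
    }
  }
  sel <- select_global_lambda(datasets, grid, k_folds = config$k_folds)
  enc <- vector("list", length(datasets))
  rows <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    res <- suppressWarnings(
      cv_evaluate(datasets[[i]], lambda = sel$lambda,
                  k_folds = config$k_folds))
    enc[[i]] <- res
    k <- keys[[i]]
    rows[[i]] <- data.frame(
      id = k$id, area = k$area, condition = k$cond,
      mean_r = res$mean_r,
      t(stats::setNames(res$fold_r, paste0("fold_r", seq_along(res$fold_r)))),
      lambda = sel$lambda, stringsAsFactors = FALSE)
  }
  enc_tab <- do.call(rbind, rows)
  write_tsv_file(enc_tab, file.path(out_dir, "encoding_results.tsv"))

  ## stage 4: stats
  meta <- cohort$metadata
  grp_of <- stats::setNames(meta$group, meta$id)
  stats_out <- list(lambda = sel$lambda)
  for (area in c("DLPFC", "pSTC")) {
    for (cond in conds) {
      sub <- enc_tab[enc_tab$area == area & enc_tab$condition == cond, ]
      g <- grp_of[sub$id]
      cell <- list()
      for (grp in unique(g)) {
        r <- sub$mean_r[g == grp]
        if (length(r) >= 2L && stats::sd(r) > 0)
          cell[[grp]] <- c(list(n = length(r), mean_r = mean(r)),
                           one_sample_t(r))
      }
      if (length(unique(g)) == 2L) {
        a <- sub$mean_r[g == "childhood"]; b <- sub$mean_r[g == "post_childhood"]
        if (length(a) >= 2L && length(b) >= 2L)
          cell$group_difference <- unpaired_t(a, b)
      }
      stats_out[[paste(area, cond, sep = "_")]] <- cell
    }
  }
  ## speech vs music paired contrast and voice effect, per area and group
  for (area in c("DLPFC", "pSTC")) {
    sp <- enc_tab[enc_tab$area == area & enc_tab$condition == "speech", ]
    mu <- enc_tab[enc_tab$area == area & enc_tab$condition == "music", ]
    common <- intersect(sp$id, mu$id)
    rs <- sp$mean_r[match(common, sp$id)]
    rm_ <- mu$mean_r[match(common, mu$id)]
    g <- grp_of[common]
    po <- g == "post_childhood"
    if (sum(po) >= 2L)
      stats_out[[paste0(area, "_speech_vs_music_post")]] <-
        paired_t(rs[po], rm_[po])
    if (length(unique(g)) == 2L && min(table(g)) >= 2L)
      stats_out[[paste0(area, "_voice_effect")]] <-
        voice_effect(rs, rm_, group = g)[c("contrast", "group_means")]
  }
  ## children's pSTC: per-participant permutation tests (speech)
  ch_pstc <- meta$id[meta$group == "childhood" & meta$n_contacts_pstc > 0]
  speech_blocks <- unique(cohort$bins$block_index[cohort$bins$condition == "speech"])
  sp_feats <- cohort$features[as.character(speech_blocks)]
  sp_rows <- cohort$bins$condition == "speech"
  perm_p <- list()
  for (pid in ch_pstc) {
    pr <- permutation_test(
      sp_feats, cohort$data[[pid]][["pSTC"]][sp_rows, , drop = FALSE],
      lambda = sel$lambda, lags = config$lags, fs_feat = config$fs_feat,
      n_perm = config$n_perm, k_folds = config$k_folds,
      seed = config$seed + match(pid, meta$id))
    perm_p[[pid]] <- list(observed_r = pr$observed_r, p = pr$p_two_tailed)
  }
  stats_out$childhood_pstc_permutation <- perm_p
  jsonlite::write_json(stats_out, file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## stage 5: weights — pSTC speech, inclusion by permutation p < alpha
  pstc_ids <- meta$id[meta$n_contacts_pstc > 0]
  profiles <- list(); pvals <- numeric(0)
  for (pid in pstc_ids) {
    i <- which(vapply(keys, function(k)
      k$id == pid && k$area == "pSTC" && k$cond == "speech", logical(1)))
    pr <- permutation_test(
      sp_feats, cohort$data[[pid]][["pSTC"]][sp_rows, , drop = FALSE],
      lambda = sel$lambda, lags = config$lags, fs_feat = config$fs_feat,
      n_perm = config$n_perm, k_folds = config$k_folds,
      seed = config$seed + 1000L + match(pid, meta$id))
    profiles[[pid]] <- list(id = pid,
                            age = meta$age[meta$id == pid],
                            weights = pool_fold_weights(enc[[i]]))
    pvals <- c(pvals, pr$p_two_tailed)
  }
  included <- filter_significant_profiles(profiles, pvals, config$alpha)
  wa <- NULL
  if (length(included) >= 3L) {
    wa <- weight_age_correlation(included, fset)
    write_tsv_file(wa$table, file.path(out_dir, "weight_age.tsv"))
  }

  manifest <- list(
    stages = c("simulate", "design", "encode", "stats", "weights"),
    config = unclass(config), seed = config$seed,
    n_datasets = length(datasets),
    lambda = sel$lambda,
    n_weight_profiles = length(included),
    package_version = as.character(utils::packageVersion("ieegencode")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cohort = cohort, encoding = enc_tab, stats = stats_out,
                 weight_age = wa, lambda = sel$lambda))
}
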