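# Stage 4 — group-level inference on prediction accuracy.
#
# Per area and condition: one-sample t tests of each group's accuracies
# against zero and the childhood vs post-childhood contrast (Student t).
# Per area: the paired speech-vs-music test in the post-childhood group and
# the voice effect (speech - music difference) contrasted between groups.
# For the children's pSTC contacts, where single small samples need
# distribution-free evidence, per-participant temporal-shuffle permutation
# tests. Writes group_stats.json.

# Run from the repository root: Rscript analysis/04_stats.R
source("analysis/common.R")

opt <- parse_args()
cfg <- analysis_config(opt$seed)
cohort <- analysis_cohort(cfg)
ds <- analysis_datasets(cohort, cfg)
grid <- ridge_lambda_grid(cfg$lambda_n, cfg$lambda_range)
sel <- select_global_lambda(ds$datasets, grid, k_folds = cfg$k_folds)

mean_r <- vapply(ds$datasets, function(d) suppressWarnings(
  cv_evaluate(d, lambda = sel$lambda, k_folds = cfg$k_folds,
              keep_weights = FALSE)$mean_r), numeric(1))
key_df <- do.call(rbind, lapply(ds$keys, as.data.frame))
key_df$mean_r <- mean_r
grp <- setNames(cohort$metadata$group, cohort$metadata$id)

out <- list(lambda = sel$lambda)
for (area in c("DLPFC", "pSTC")) {
  for (cond in ds$conds) {
    sub <- key_df[key_df$area == area & key_df$cond == cond, ]
    g <- grp[sub$id]
    cell <- list()
    for (gr in unique(g)) {
      r <- sub$mean_r[g == gr]
      if (length(r) >= 2 && sd(r) > 0)
        cell[[gr]] <- c(list(n = length(r), mean_r = mean(r)), one_sample_t(r))
    }
    if (length(unique(g)) == 2)
      cell$group_difference <- unpaired_t(sub$mean_r[g == "childhood"],
                                          sub$mean_r[g == "post_childhood"])
    out[[paste(area, cond, sep = "_")]] <- cell
  }
  sp <- key_df[key_df$area == area & key_df$cond == "speech", ]
  mu <- key_df[key_df$area == area & key_df$cond == "music", ]
  common <- intersect(sp$id, mu$id)
  rs <- sp$mean_r[match(common, sp$id)]
  rm_ <- mu$mean_r[match(common, mu$id)]
  g <- grp[common]
  po <- g == "post_childhood"
  if (sum(po) >= 2)
    out[[paste0(area, "_speech_vs_music_post")]] <- paired_t(rs[po], rm_[po])
  if (length(unique(g)) == 2 && min(table(g)) >= 2)
    out[[paste0(area, "_voice_effect")]] <-
      voice_effect(rs, rm_, group = g)[c("contrast", "group_means")]
}

# children's pSTC permutation tests (speech condition)
meta <- cohort$metadata
ch_pstc <- meta$id[meta$group == "childhood" & meta$n_contacts_pstc > 0]
sp_rows <- cohort$bins$condition == "speech"
sp_blocks <- unique(cohort$bins$block_index[sp_rows])
sp_feats <- cohort$features[as.character(sp_blocks)]
out$childhood_pstc_permutation <- lapply(setNames(ch_pstc, ch_pstc),
  function(pid) {
    pr <- permutation_test(sp_feats,
                           cohort$data[[pid]][["pSTC"]][sp_rows, , drop = FALSE],
                           lambda = sel$lambda, lags = cfg$lags,
                           fs_feat = cfg$fs_feat, n_perm = cfg$n_perm,
                           k_folds = cfg$k_folds,
                           seed = opt$seed + match(pid, meta$id))
    list(observed_r = pr$observed_r, p = pr$p_two_tailed)
  })

jsonlite::write_json(out, file.path(opt$out, "group_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
for (nm in c("DLPFC_speech", "pSTC_speech")) {
  cell <- out[[nm]]
  for (gr in intersect(names(cell), c("childhood", "post_childhood")))
    cat(sprintf("%s %s: n=%d mean r=%.3f t=%.3f df=%d p=%.4g\n", nm, gr,
                cell[[gr]]$n, cell[[gr]]$mean_r, cell[[gr]]$t,
                cell[[gr]]$df, cell[[gr]]$p))
}
for (pid in names(out$childhood_pstc_permutation)) {
  pr <- out$childhood_pstc_permutation[[pid]]
  cat(sprintf("perm %s: r=%.3f p=%.4g\n", pid, pr$observed_r, pr$p))
}
cat(sprintf("wrote group_stats.json to %s\n", opt$out))
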