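# Stage 3 — fit the time-lagged ridge encoding models.
#
# Builds per-condition lagged design matrices (48 features x lags 0/0.5/1 s),
# concatenates contacts within each area, selects ONE ridge penalty for the
# whole study (the grid value maximizing mean cross-validated accuracy over
# all participant x area x condition datasets), then evaluates every dataset
# with 5-fold cross-validation. Writes encoding_results.tsv: one row per
# dataset with per-fold and mean prediction accuracy (Pearson r).

# Run from the repository root: Rscript analysis/03_encode.R
source("analysis/common.R")

opt <- parse_args()
cfg <- analysis_config(opt$seed)
cohort <- analysis_cohort(cfg)
ds <- analysis_datasets(cohort, cfg)
grid <- ridge_lambda_grid(cfg$lambda_n, cfg$lambda_range)

sel <- select_global_lambda(ds$datasets, grid, k_folds = cfg$k_folds)
cat(sprintf("global penalty: lambda = %.4g (over %d datasets)\n",
            sel$lambda, length(ds$datasets)))

rows <- lapply(seq_along(ds$datasets), function(i) {
  res <- suppressWarnings(cv_evaluate(ds$datasets[[i]], lambda = sel$lambda,
                                      k_folds = cfg$k_folds,
                                      keep_weights = FALSE))
  k <- ds$keys[[i]]
  data.frame(id = k$id, area = k$area, condition = k$cond,
             mean_r = res$mean_r,
             t(setNames(res$fold_r, paste0("fold_r", seq_along(res$fold_r)))),
             lambda = sel$lambda, stringsAsFactors = FALSE)
})
enc <- do.call(rbind, rows)
write.table(enc, file.path(opt$out, "encoding_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

enc_grouped <- enc
enc_grouped$group <- setNames(cohort$metadata$group, cohort$metadata$id)[enc$id]
summ <- aggregate(mean_r ~ area + condition + group, enc_grouped, mean)
print(summ, row.names = FALSE)
cat(sprintf("wrote encoding_results.tsv (%d rows) to %s\n", nrow(enc), opt$out))
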