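# Stage 5 — encoding weights versus age.
#
# For every pSTC participant whose speech-condition accuracy beats the
# temporal-shuffle null (permutation p < alpha), pools the cross-validation
# fold weights into 48 absolute per-feature weights, then correlates each
# feature's weight with age across the included participants. Features are
# ranked by correlation; the complex-emotion (guilt, embarrassment, pride,
# envy) and basic-emotion aggregates are tested on the aggregated weights.
# Writes weight_age.tsv and weight_age_summary.json.

# Run from the repository root: Rscript analysis/05_weight_age.R
source("analysis/common.R")

opt <- parse_args()
cfg <- analysis_config(opt$seed)
cohort <- analysis_cohort(cfg)
ds <- analysis_datasets(cohort, cfg)
grid <- ridge_lambda_grid(cfg$lambda_n, cfg$lambda_range)
sel <- select_global_lambda(ds$datasets, grid, k_folds = cfg$k_folds)

meta <- cohort$metadata
pstc_ids <- meta$id[meta$n_contacts_pstc > 0]
sp_rows <- cohort$bins$condition == "speech"
sp_blocks <- unique(cohort$bins$block_index[sp_rows])
sp_feats <- cohort$features[as.character(sp_blocks)]

profiles <- list(); pvals <- numeric(0)
for (pid in pstc_ids) {
  i <- which(vapply(ds$keys, function(k)
    k$id == pid && k$area == "pSTC" && k$cond == "speech", logical(1)))
  res <- suppressWarnings(cv_evaluate(ds$datasets[[i]], lambda = sel$lambda,
                                      k_folds = cfg$k_folds))
  pr <- permutation_test(sp_feats,
                         cohort$data[[pid]][["pSTC"]][sp_rows, , drop = FALSE],
                         lambda = sel$lambda, lags = cfg$lags,
                         fs_feat = cfg$fs_feat, n_perm = cfg$n_perm,
                         k_folds = cfg$k_folds,
                         seed = opt$seed + 1000L + match(pid, meta$id))
  profiles[[pid]] <- list(id = pid, age = meta$age[meta$id == pid],
                          weights = pool_fold_weights(res))
  pvals <- c(pvals, pr$p_two_tailed)
}
included <- filter_significant_profiles(profiles, pvals, cfg$alpha)
cat(sprintf("included %d of %d pSTC participants (permutation p < %.2f)\n",
            length(included), length(profiles), cfg$alpha))
if (length(included) < 3) stop("too few significant participants to rank")

wa <- weight_age_correlation(included)
write.table(wa$table, file.path(opt$out, "weight_age.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n = wa$n, complex_r = wa$complex_r, complex_p = wa$complex_p,
       basic_r = wa$basic_r, basic_p = wa$basic_p),
  file.path(opt$out, "weight_age_summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("complex aggregate: r=%.3f p=%.4g | basic aggregate: r=%.3f p=%.4g (n=%d)\n",
            wa$complex_r, wa$complex_p, wa$basic_r, wa$basic_p, wa$n))
cat("top of the ranking:\n")
print(head(wa$table, 8), row.names = FALSE)
cat(sprintf("wrote weight_age.tsv, weight_age_summary.json to %s\n", opt$out))
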