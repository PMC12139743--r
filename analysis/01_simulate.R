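# Stage 1 — simulate the synthetic cohort.
#
# Builds the study-shaped cohort (11 children, 31 post-childhood; DLPFC and
# pSTC coverage; 4 contacts per covered area) watching a simulated 13-block
# movie, with known ground-truth encoding weights. Writes the tabular
# artifacts every later stage keys on: the block schedule, participant
# metadata, and one example block's feature timecourses.

# Run from the repository root: Rscript analysis/01_simulate.R
source("analysis/common.R")

opt <- parse_args()
cfg <- analysis_config(opt$seed)
cohort <- analysis_cohort(cfg)

write_events_tsv(cohort$schedule, file.path(opt$out, "events.tsv"))
write_metadata_tsv(cohort$metadata, file.path(opt$out, "metadata.tsv"))
first_block <- names(cohort$features)[1]
write_features_csv(cohort$features[[first_block]],
                   file.path(opt$out, sprintf("features_block%s.csv",
                                              first_block)))

n_music <- sum(cohort$schedule$trial_type == "music")
n_speech <- sum(cohort$schedule$trial_type == "speech")
cat(sprintf("cohort: %d participants (%d childhood, %d post-childhood)\n",
            nrow(cohort$metadata),
            sum(cohort$metadata$group == "childhood"),
            sum(cohort$metadata$group == "post_childhood")))
cat(sprintf("schedule: %d blocks (%d music, %d speech), %d feature-present\n",
            nrow(cohort$schedule), n_music, n_speech,
            sum(cohort$schedule$features_present)))
cat(sprintf("wrote events.tsv, metadata.tsv, features_block%s.csv to %s\n",
            first_block, opt$out))
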