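# Stage 2 — preprocess raw voltage traces to binned HFB amplitude.
#
# The encoding stages work on binned HFB responses, which the simulator
# produces directly. This stage demonstrates the raw-signal path: it wraps
# one participant's generative HFB targets in an amplitude-modulated
# 110-140 Hz carrier with 50 Hz line noise and a pink-noise floor, then runs
# the full extraction chain (notch -> common average reference -> band-pass
# + Hilbert envelope -> epoch -> 400 Hz -> sqrt -> baseline z-score) and
# reports how well the binned output matches the generative target.

# Run from the repository root: Rscript analysis/02_preprocess.R
source("analysis/common.R")

opt <- parse_args()
cfg <- analysis_config(opt$seed)
cohort <- analysis_cohort(cfg)

pid <- cohort$metadata$id[which(cohort$metadata$n_contacts_pstc > 0)[1]]
binned_true <- cohort$data[[pid]][["pSTC"]]
fp <- cohort$schedule[cohort$schedule$features_present, ]
per_block <- function(y)
  unname(split(y, rep(seq_len(nrow(fp)), each = length(y) / nrow(fp))))
targets <- lapply(seq_len(ncol(binned_true)), function(ch)
  per_block(binned_true[, ch]))

session <- synthesize_raw_signal(targets, cohort$schedule, fs_raw = 1000,
                                 carrier_band = cfg$band, gain = 0.5,
                                 line_amp = 0.5, pink_sd = 0.3,
                                 fs_target = cfg$fs_feat, seed = opt$seed)
epochs <- preprocess_session(session, cohort$schedule, band = cfg$band,
                             notch_freq = cfg$notch,
                             target_fs = cfg$target_fs)
recovered <- bin_response(epochs, bin = cfg$bin)

# per-contact, per-block correlation with the generative target (each block
# is an independently baseline-normalized epoch)
n_bins <- nrow(recovered) / nrow(fp)
r_tab <- do.call(rbind, lapply(seq_len(ncol(recovered)), function(ch) {
  r_b <- vapply(seq_len(nrow(fp)), function(b) {
    idx <- (b - 1) * n_bins + seq_len(n_bins)
    cor(recovered[idx, ch], binned_true[idx, ch])
  }, numeric(1))
  data.frame(contact = colnames(binned_true)[ch], mean_r = mean(r_b),
             min_r = min(r_b), stringsAsFactors = FALSE)
}))
write.table(r_tab, file.path(opt$out, "preprocess_roundtrip.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("participant %s, %d contacts, %d blocks\n", pid,
            ncol(recovered), nrow(fp)))
print(r_tab, row.names = FALSE)
cat(sprintf("wrote preprocess_roundtrip.tsv to %s\n", opt$out))
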