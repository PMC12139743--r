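# Shared setup for the numbered analysis scripts.
#
# Every script can be run on its own:
#   Rscript analysis/01_simulate.R [--seed N] [--out DIR]
# Stages regenerate what they need from the same seed instead of passing
# serialized state, so each script is deterministic and idempotent.

suppressPackageStartupMessages(library(ieegencode))

parse_args <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- list(seed = 1L, out = "results")
  i <- 1L
  while (i <= length(args)) {
    if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
    else if (args[i] == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
    else stop("unknown argument: ", args[i])
  }
  if (is.na(opt$seed)) stop("--seed must be an integer")
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  opt
}

# Desk-scale analysis configuration: the study-shaped 42-participant cohort
# with 4 contacts per covered area, and 199 permutation iterations (the
# permutation p-value floor 1/200 is well below the 0.05 inclusion
# threshold, at a fraction of the full 5000-iteration cost).
analysis_config <- function(seed) {
  pipeline_config(seed = seed, n_perm = 199,
                  cohort = list(n_contacts = 4, complex_age_slope = 0.05))
}

# The cohort every stage operates on, regenerated deterministically.
analysis_cohort <- function(cfg) {
  spec <- default_cohort_spec(n_contacts = 4, complex_age_slope = 0.05,
                              seed = cfg$seed)
  generate_cohort(spec, seed = cfg$seed, lags = cfg$lags,
                  fs_feat = cfg$fs_feat)
}

# Per-condition lagged designs and the per-dataset (participant x area x
# condition) regression problems shared by the encode/stats/weights stages.
analysis_datasets <- function(cohort, cfg) {
  conds <- unique(cohort$bins$condition)
  designs <- lapply(conds, function(cond) {
    keep <- cohort$bins$condition == cond
    blocks <- unique(cohort$bins$block_index[keep])
    X <- build_lagged_design(cohort$features[as.character(blocks)],
                             cfg$lags, cfg$fs_feat)
    list(X = X, rows = keep)
  })
  names(designs) <- conds
  datasets <- list(); keys <- list()
  for (pid in names(cohort$data)) {
    for (area in names(cohort$data[[pid]])) {
      for (cond in conds) {
        d <- designs[[cond]]
        datasets[[length(datasets) + 1L]] <- concatenate_contacts(
          cohort$data[[pid]][[area]][d$rows, , drop = FALSE], d$X)
        keys[[length(keys) + 1L]] <- list(id = pid, area = area, cond = cond)
      }
    }
  }
  list(designs = designs, datasets = datasets, keys = keys, conds = conds)
}
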