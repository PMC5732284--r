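#!/usr/bin/env Rscript
# Export the four unconvolved parametric regressor time series per session
# (value and entropy at stimulus onset, transition indicator at stimulus
# onset, reward prediction error at feedback onset for go trials), from the
# inherited-value transfer model and the softmax-based search.

library(polexplore)

sess_dir <- file.path("results", "sessions")
search_dir <- file.path("results", "search")
fits_path <- file.path("results", "fits", "model_fits.tsv")
out_dir <- file.path("results", "regressors")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fit_table <- utils::read.delim(fits_path)
inh <- fit_table[fit_table$model == "transfer_inherited", ]

files <- sort(list.files(sess_dir, pattern = "^session_.*\\.tsv$",
                         full.names = TRUE))
for (f in files) {
  id <- sub("\\.tsv$", "", basename(f))
  trials <- read_session(f)
  search <- readRDS(file.path(search_dir, paste0(id, "_search.rds")))$softmax
  pr <- inh[inh$session == id, ]
  vt <- run_value_transfer(trials, search$current_policy,
                           learning_params(pr$alpha, pr$beta), "inherited")
  export_regressors(trials, vt, search,
                    file.path(out_dir, paste0(id, "_regressors.tsv")))
  export_model_trace(vt, file.path(out_dir, paste0(id, "_trace.tsv")))
}
cat(sprintf("Wrote regressors for %d sessions to %s\n", length(files),
            out_dir))
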