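#!/usr/bin/env Rscript
# Stage 1 + 2 of the analysis: fit the seven per-policy learning parameters
# to every session, infer per-trial policy posteriors with both search
# models (softmax-based and HMM-based), smooth, extract the current policy,
# transitions, entropy and strategy class. Writes per-session posterior
# tables and a cohort summary.

library(polexplore)

sess_dir <- file.path("results", "sessions")
out_dir <- file.path("results", "search")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- sort(list.files(sess_dir, pattern = "^session_.*\\.tsv$",
                         full.names = TRUE))
stopifnot(length(files) > 0)

rows <- list()
for (f in files) {
  id <- sub("\\.tsv$", "", basename(f))
  trials <- read_session(f)
  stage1 <- lapply(1:7, function(i) fit_policy(trials, get_policy(i)))
  rl <- lapply(1:7, function(i)
    run_naive_rl(trials, get_policy(i), stage1[[i]]$params))
  sm <- run_policy_search(trials, rl, "softmax")
  hm <- run_policy_search(trials, rl, "hmm")
  export_posterior(sm, file.path(out_dir, paste0(id, "_softmax.tsv")))
  export_posterior(hm, file.path(out_dir, paste0(id, "_hmm.tsv")))
  saveRDS(list(stage1 = stage1, softmax = sm, hmm = hm),
          file.path(out_dir, paste0(id, "_search.rds")))
  rows[[id]] <- data.frame(
    session = id,
    strategy = sm$strategy,
    n_transitions = nrow(sm$transitions),
    mean_entropy = mean(sm$entropy),
    logL_softmax = sm$logL,
    logL_hmm = hm$logL)
  cat(sprintf("%s: strategy %-9s transitions %2d\n",
              id, sm$strategy, nrow(sm$transitions)))
}
summary_df <- do.call(rbind, rows)
utils::write.table(summary_df, file.path(out_dir, "search_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Strategy classes:\n")
print(table(summary_df$strategy))
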