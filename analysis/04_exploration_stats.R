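#!/usr/bin/env Rscript
# Exploration statistics: entropy at policy-transition trials versus all
# trials (paired across sessions), the pooled regression of
# entropy-at-transition on trial index, and the correlation between
# transfer-model likelihood and task performance.

library(polexplore)

sess_dir <- file.path("results", "sessions")
search_dir <- file.path("results", "search")
fits_path <- file.path("results", "fits", "model_fits.tsv")
out_dir <- file.path("results", "exploration")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- sort(list.files(sess_dir, pattern = "^session_.*\\.tsv$",
                         full.names = TRUE))
sessions <- list(); pooled <- list(); scores <- numeric(0)
for (f in files) {
  id <- sub("\\.tsv$", "", basename(f))
  trials <- read_session(f)
  scores[id] <- sum(trials$reward)
  search <- readRDS(file.path(search_dir, paste0(id, "_search.rds")))
  sm <- search$softmax
  sessions[[id]] <- list(entropy = sm$entropy, transitions = sm$transitions)
  if (nrow(sm$transitions) > 0) {
    pooled[[id]] <- data.frame(
      session = id,
      trial_index = sm$transitions$trial_index,
      entropy = sm$entropy[sm$transitions$trial_index])
  }
}

tet <- transition_entropy_test(sessions)
cat(sprintf(
  "Entropy at transitions minus overall: %+0.4f nats (t = %.2f, df = %d, p = %.4g; %d sessions used, %d without transitions)\n",
  tet$mean_diff, tet$t, tet$df, tet$p, tet$n_included, tet$n_excluded))

pooled_df <- do.call(rbind, pooled)
utils::write.table(pooled_df, file.path(out_dir, "pooled_transitions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
reg <- transition_timing_regression(pooled_df)
cat(sprintf(
  "Entropy-at-transition on trial index: slope %+0.5f, R^2 = %.3f, p = %.4g (n = %d transitions)\n",
  reg$slope, reg$r_squared, reg$p, reg$n))

fit_table <- utils::read.delim(fits_path)
inh <- fit_table[fit_table$model == "transfer_inherited", ]
inh <- inh[order(inh$session), ]
lp <- likelihood_performance_correlation(inh$logL, scores[inh$session])
cat(sprintf(
  "Score on transfer-model logL: slope %+0.3f, R^2 = %.3f, p = %.4g\n",
  lp$slope, lp$r_squared, lp$p))

res <- data.frame(
  statistic = c("entropy_diff", "entropy_diff_p", "timing_slope",
                "timing_r2", "timing_p", "likperf_slope", "likperf_r2",
                "likperf_p"),
  value = c(tet$mean_diff, tet$p, reg$slope, reg$r_squared, reg$p,
            lp$slope, lp$r_squared, lp$p))
utils::write.table(res, file.path(out_dir, "exploration_stats.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
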