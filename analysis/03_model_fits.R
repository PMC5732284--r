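#!/usr/bin/env Rscript
# Stage 3: fit all five models to every session (the value-transfer models
# with the softmax-search schedule frozen), and tabulate the cohort model
# comparison in the style of an overall model-comparison table.

library(polexplore)

sess_dir <- file.path("results", "sessions")
search_dir <- file.path("results", "search")
out_dir <- file.path("results", "fits")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- sort(list.files(sess_dir, pattern = "^session_.*\\.tsv$",
                         full.names = TRUE))
rows <- list()
fits_by_model <- list()
for (f in files) {
  id <- sub("\\.tsv$", "", basename(f))
  trials <- read_session(f)
  search <- readRDS(file.path(search_dir, paste0(id, "_search.rds")))
  stage1 <- search$stage1
  sched <- search$softmax$current_policy
  fits <- list(
    naive_softmax_search = fit_model(trials, "naive_softmax_search",
                                     stage1 = stage1),
    naive_hmm_search = fit_model(trials, "naive_hmm_search",
                                 stage1 = stage1),
    transfer_inherited = fit_model(trials, "transfer_inherited",
                                   schedule = sched),
    transfer_zero = fit_model(trials, "transfer_zero", schedule = sched),
    policy7_noise = fit_model(trials, "policy7_noise"))
  for (m in names(fits)) {
    ft <- fits[[m]]
    fits_by_model[[m]] <- c(fits_by_model[[m]], list(ft))
    pr <- if (inherits(ft$params, "learning_params")) ft$params
          else list(alpha = NA_real_, beta = NA_real_)
    rows[[paste(id, m)]] <- data.frame(
      session = id, model = m,
      alpha = pr$alpha, beta = pr$beta,
      epsilon = if (is.null(ft$epsilon)) NA_real_ else ft$epsilon,
      logL = ft$logL, k = ft$k, n = ft$n, aic = ft$aic, bic = ft$bic)
  }
  cat(id, "fitted\n")
}
fit_table <- do.call(rbind, rows)
utils::write.table(fit_table, file.path(out_dir, "model_fits.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# cohort means per model (analogue of an overall comparison table)
agg <- stats::aggregate(cbind(logL, aic, bic) ~ model, data = fit_table, mean)
utils::write.table(agg, file.path(out_dir, "model_means.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(agg)

# paired comparisons of the main contrasts
contrasts <- list(c("transfer_inherited", "transfer_zero"),
                  c("transfer_inherited", "naive_softmax_search"),
                  c("transfer_inherited", "policy7_noise"),
                  c("naive_softmax_search", "naive_hmm_search"))
cmp_rows <- list()
for (ct in contrasts) {
  for (crit in c("aic", "bic")) {
    cc <- compare_models(fits_by_model[[ct[1]]], fits_by_model[[ct[2]]], crit)
    cmp_rows[[paste(ct[1], ct[2], crit)]] <- data.frame(
      model_a = ct[1], model_b = ct[2], criterion = crit,
      mean_diff = cc$mean_diff, t = cc$t, df = cc$df, p = cc$p)
    cat(sprintf("%s vs %s (%s): mean diff %.2f, p = %.4g\n",
                ct[1], ct[2], crit, cc$mean_diff, cc$p))
  }
}
utils::write.table(do.call(rbind, cmp_rows),
                   file.path(out_dir, "model_comparisons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
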