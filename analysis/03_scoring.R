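#!/usr/bin/env Rscript
# Stage 3: NPT response scoring, d-prime, and group comparisons of the
# behavioural counts.

suppressPackageStartupMessages(library(nptfrp))
st <- readRDS("scratch/study.rds")
study <- st$study

scores <- score_sessions(study)
write.csv(scores, "results/scores.csv", row.names = FALSE)

message("per-group means:")
for (g in unique(scores$group)) {
  s <- scores[scores$group == g, ]
  message(sprintf("  %-4s pareidolias %5.1f  missed %4.1f  d' %4.2f",
                  g, mean(s$n_pareidolia), mean(s$n_missed),
                  mean(s$d_prime)))
}

kp <- kruskal_dunn(scores$n_pareidolia, scores$group)
kd <- kruskal_dunn(scores$d_prime, scores$group)
message(sprintf("pareidolia counts: H(%g) = %.2f, p = %.4g",
                kp$df, kp$H, kp$p))
message(sprintf("d-prime:           H(%g) = %.2f, p = %.4g",
                kd$df, kd$H, kd$p))

out <- list(
  pareidolia = list(H = kp$H, df = kp$df, p = kp$p, dunn = kp$dunn),
  d_prime = list(H = kd$H, df = kd$df, p = kd$p, dunn = kd$dunn))
jsonlite::write_json(out, "results/npt_stats.json", auto_unbox = TRUE,
                     digits = NA, force = TRUE)
message("wrote results/scores.csv and results/npt_stats.json")
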