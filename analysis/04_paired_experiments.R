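#!/usr/bin/env Rscript
# Paired-simulation output-invariance experiments.
#
# Drives the model with the shared step-and-noise schedule (reference
# r: 11 -> 16 -> 13.75, disturbance d: 0.01 -> 5, sd-1 noise on the
# varying windows) and compares the output y(t) between runs differing
# only in one parameter:
#   s: 0.25 vs 1.5  (strict protocol: z(0) scaled by s1/s2, and the
#                    after-adaptation protocol with identical states)
#   b: 0.3 vs 0.6
#   c: 2 vs 4
#
# Findings: the s-pair outputs coincide to solver precision (invariant);
# the b- and c-pairs separate by O(1) during transients (not invariant),
# though the c-pair re-converges at the end because both runs settle to
# y = r.

library(adaptivePI)

out_dir <- "results/04_paired"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

experiments <- list(
  list(pn = "s", p1 = 0.25, p2 = 1.5, protocol = "strict"),
  list(pn = "s", p1 = 0.25, p2 = 1.5, protocol = "dc_after_adaptation"),
  list(pn = "b", p1 = 0.3, p2 = 0.6, protocol = "strict"),
  list(pn = "c", p1 = 2, p2 = 4, protocol = "strict"))

summary_rows <- list()
for (ex in experiments) {
  rep <- paired_output_test(ex$pn, ex$p1, ex$p2, protocol = ex$protocol,
                            shared_seed = seed)
  print(rep)
  tag <- sprintf("%s_%s", ex$pn, ex$protocol)
  invariance_report_to_files(
    rep, file.path(out_dir, paste0(tag, ".json")),
    file.path(out_dir, paste0(tag, "_dy.csv")))
  summary_rows[[tag]] <- data.frame(
    parameter = ex$pn, p1 = ex$p1, p2 = ex$p2, protocol = ex$protocol,
    max_abs_dy = rep$max_abs_output_diff,
    terminal_abs_dy = rep$terminal_abs_output_diff,
    verdict = rep$verdict)

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    library(ggplot2)
    keep <- seq(1, length(rep$times), by = 25)
    df <- data.frame(t = rep$times[keep], y1 = rep$y1[keep],
                     y2 = rep$y2[keep], dy = rep$dy[keep])
    g <- ggplot(df, aes(t)) +
      geom_line(aes(y = y1, colour = "run 1")) +
      geom_line(aes(y = y2, colour = "run 2"), linetype = 2) +
      geom_line(aes(y = dy, colour = "difference"), linetype = 3) +
      labs(title = sprintf("%s: %g vs %g (%s) — %s", ex$pn, ex$p1, ex$p2,
                           ex$protocol, rep$verdict),
           x = "time", y = "output y(t)", colour = NULL) +
      theme_minimal()
    ggsave(file.path(out_dir, paste0(tag, ".png")), g,
           width = 6, height = 3.5, dpi = 150)
  }
}
tab <- do.call(rbind, summary_rows)
rownames(tab) <- NULL
write.csv(tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
cat("\n")
print(tab)
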