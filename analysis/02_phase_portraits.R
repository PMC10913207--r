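#!/usr/bin/env Rscript
# Phase portraits of the adaptive PI model at the four parameter sets.
#
# Samples the (y, z) vector field on a 15x15 grid over [0, 20] x [0, 10]
# and integrates one trajectory per node (horizon 60). Findings: for every
# parameter set, all sampled trajectories with z(0) > 0 converge to the
# tracking equilibrium E2; changing s moves E2 vertically (z scales by
# 1/s) but leaves the attained output y = r unchanged, while changing b
# or c reshapes the transient.

library(adaptivePI)

out_root <- "results/02_phase_portraits"
sc <- baseline_scenario()
sets <- study_param_sets()

for (nm in names(sets)) {
  cfg <- experiment_config("phase_portrait", sets[[nm]],
                           r0 = sc$r0, d0 = sc$d0, seed = 1,
                           out_dir = file.path(out_root, nm),
                           grid_n = 15, horizon = 60)
  man <- run_experiment(cfg)
  pp <- attr(man, "result")
  ends <- read.csv(file.path(out_root, nm, "trajectory_endpoints.csv"))
  interior <- ends$z0 > 0
  dist <- sqrt((ends$y_end - pp$equilibria$E2$point[["y"]])^2 +
                 (ends$z_end - pp$equilibria$E2$point[["z"]])^2)
  cat(sprintf(
    "%-9s E2 = (%.3f, %.3f); %d/%d interior trajectories within 1e-2\n",
    nm, pp$equilibria$E2$point[["y"]], pp$equilibria$E2$point[["z"]],
    sum(dist[interior] < 1e-2), sum(interior)))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    library(ggplot2)
    fld <- pp$field
    nrm <- sqrt(fld$dy^2 + fld$dz^2)
    sc_len <- 0.5 / stats::median(nrm)
    g <- ggplot(fld, aes(y, z)) +
      geom_segment(aes(xend = y + sc_len * dy, yend = z + sc_len * dz),
                   arrow = arrow(length = unit(1.2, "mm")),
                   linewidth = 0.2, colour = "grey50") +
      annotate("point", x = pp$equilibria$E1$point[["y"]],
               y = pp$equilibria$E1$point[["z"]], colour = "red") +
      annotate("point", x = pp$equilibria$E2$point[["y"]],
               y = pp$equilibria$E2$point[["z"]], colour = "red") +
      labs(title = sprintf("Phase portrait (%s)", nm),
           x = "output y", y = "adapting state z") +
      theme_minimal()
    ggsave(file.path(out_root, nm, "portrait.png"), g,
           width = 5, height = 4, dpi = 150)
  }
}
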