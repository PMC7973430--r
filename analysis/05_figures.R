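#!/usr/bin/env Rscript

# Step 5 — figures from the tables written by steps 2-4.

suppressPackageStartupMessages({
  library(ggplot2)
  library(motionsalience)
})
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

profiles <- read.csv("results/display_extent.csv")
p1 <- ggplot(profiles, aes(frame, extent)) +
  geom_line(linewidth = 0.3) +
  facet_wrap(~display, ncol = 1, scales = "free_y") +
  labs(x = "frame", y = "motion extent (cells)",
       title = "Temporal structure of the display archetypes") +
  theme_minimal(base_size = 9)
ggsave("results/figures/display_structure.pdf", p1, width = 5, height = 6)

res <- read.csv("results/factorial.csv")
p2 <- ggplot(res, aes(factor(wind_level), moderate)) +
  geom_boxplot(outlier.size = 0.4) +
  facet_wrap(~habitat) +
  labs(x = "wind level", y = "proportion exceeding threshold",
       title = "Moderate-threshold performance vs wind, by habitat") +
  theme_minimal(base_size = 9)
ggsave("results/figures/performance_vs_wind.pdf", p2, width = 7, height = 5)

coords <- read.csv("results/nmds_coordinates.csv")
p3 <- ggplot(coords, aes(NMDS1, NMDS2, colour = habitat, shape = display)) +
  geom_point(size = 1.6) +
  facet_wrap(~band) +
  labs(title = "NMDS of performance vectors by wind band") +
  theme_minimal(base_size = 9)
ggsave("results/figures/nmds.pdf", p3, width = 9, height = 3.5)

cat("figures written to results/figures/\n")
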