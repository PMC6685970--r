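#!/usr/bin/env Rscript
# Group statistics: (a) the published class I / class II per-section OSN
# quantifications recomputed from their summary statistics; (b) t-tests with
# BH adjustment on a simulated multi-gene count panel; (c) pseudocount fold
# changes and a dorsal-ventral distribution example.

suppressPackageStartupMessages(library(olfmap))

seed <- 20260919L
out <- "results/stats"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## (a) published summaries: mean +/- s.e.m., n = 3 per group
published <- rbind(
  data.frame(comparison = "class_I",  m1 = 33.8, sem1 = 1.60, m2 = 3.78, sem2 = 1.82),
  data.frame(comparison = "class_II", m1 = 25.6, sem1 = 1.57, m2 = 26.4, sem2 = 3.15)
)
res <- do.call(rbind, lapply(seq_len(nrow(published)), function(i) {
  p <- published[i, ]
  do.call(rbind, lapply(c("welch", "pooled"), function(fl) {
    r <- ttest_from_summary(p$m1, p$sem1, 3, p$m2, p$sem2, 3, flavor = fl)
    data.frame(comparison = p$comparison, flavor = fl,
               t = r$t, df = r$df, p = r$p)
  }))
}))
write.csv(res, file.path(out, "published_recomputed.csv"), row.names = FALSE)
cat("recomputed published comparisons:\n"); print(res)

## (b) simulated per-gene panel: 12 genes, half with a true group effect
set.seed(seed)
genes <- sprintf("OR%02d", 1:12)
effect <- rep(c(0, 0.4), each = 6)        # multiplicative change in the mean
panel <- do.call(rbind, lapply(seq_along(genes), function(g) {
  ctrl <- gen_counts(count_spec(lambda = c(control = 30),
                                sections_per_animal = 8, animals_per_group = 4,
                                seed = seed + 10 * g))
  mut <- gen_counts(count_spec(lambda = c(mutant = 30 * (1 - effect[g])),
                               sections_per_animal = 8, animals_per_group = 4,
                               seed = seed + 10 * g + 5))
  s1 <- summarize_counts(ctrl); s2 <- summarize_counts(mut)
  r <- ttest_from_summary(s1$mean, s1$sem, s1$n, s2$mean, s2$sem, s2$n)
  data.frame(gene = genes[g], true_effect = effect[g],
             mean_ctrl = s1$mean, mean_mut = s2$mean, p = r$p)
}))
panel$p_bh <- bh_adjust(panel$p)
write.csv(panel, file.path(out, "gene_panel_tests.csv"), row.names = FALSE)
cat(sprintf("BH-significant genes at q < 0.05: %d of %d (true effects: %d)\n",
            sum(panel$p_bh < 0.05), nrow(panel), sum(effect > 0)))

## (c) fold changes with the +0.1 pseudocount; log2 internal-control norm
set.seed(seed + 1)
fpkm_ctrl <- round(rexp(10, 1 / 5), 2)
fpkm_mut <- round(fpkm_ctrl * exp(rnorm(10, -0.5, 0.4)), 2)
fc <- cbind(gene = sprintf("OR%02d", 1:10),
            ctrl = fpkm_ctrl, mut = fpkm_mut,
            fold_change_pseudo(fpkm_mut, fpkm_ctrl))
write.csv(fc, file.path(out, "fold_changes.csv"), row.names = FALSE)

## dorsal-ventral distribution of simulated positions along the septum
pos <- pmin(abs(rnorm(200, 0.35, 0.2)), 1)
dv <- dv_distribution(pos, 1)
write.csv(data.frame(segment = 1:10, cells = dv),
          file.path(out, "dv_distribution.csv"), row.names = FALSE)

write_manifest(file.path(out, "manifest.json"),
               list(panel_genes = length(genes), alpha = 0.05,
                    bh_family = "gene panel", pseudocount = 0.1), seed)
cat("stats ->", out, "\n")
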