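#!/usr/bin/env Rscript

## Summarize the simulated WGBS call sets the way genome-wide methylome
## studies do: restrict to commonly covered CpGs, 500-CpG bins and their
## per-stage medians, 100-kb chromosome traces, per-feature aggregation
## (exons, introns, intergenic, CGIs, L1s, promoters, imprinted DMRs) and
## 5-kb coverage windows normalized to the largest sample.

suppressPackageStartupMessages(library(meiometh))

in_dir <- "results/simulation"
out_dir <- "results/wgbs"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
stages <- c("Spg", "PL", "L", "Z", "P")

calls <- lapply(stages, function(st)
  read_bismark_cov(file.path(in_dir, sprintf("%s.cov", st))))
names(calls) <- stages
common <- restrict_common(calls)
cat(sprintf("Common-CpG restriction retained %.1f%% of covered CpGs per sample\n",
            100 * min(common$retained)))
calls <- common$callsets

## 500-CpG bins, stage medians (the genome-wide methylation trajectory)
medians <- do.call(rbind, lapply(stages, function(st) {
  bm <- bin_mean(calls[[st]], k = 500L)
  data.frame(stage = st, median_meth = median(bm$mean_meth),
             q1 = quantile(bm$mean_meth, 0.25), q3 = quantile(bm$mean_meth, 0.75))
}))
write.table(medians, file.path(out_dir, "stage_bin_medians.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPer-stage median of 500-CpG bin means:\n")
print(medians, row.names = FALSE)

## 100-kb chromosome traces
for (st in stages) {
  w <- window_mean(calls[[st]], width = 100000L)
  write.table(w, file.path(out_dir, sprintf("%s_100kb.tsv", st)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

## feature aggregation on the layout the simulation used
layout <- sim_layout(seed = 20260901L + 1L)  # same derived seed as the series
ann <- c(layout$annotation,
         list(promoter = promoter_intervals(layout$annotation$gene)))
imprinted <- imprinted_dmr_annotation(layout)
feat <- do.call(rbind, lapply(stages, function(st) {
  fs <- feature_aggregate(calls[[st]], ann, chunk = 100L)
  ## imprinted DMR lists are small (11 maternal + 3 paternal loci); use a
  ## chunk matching their per-locus CpG count so none are dropped
  fi <- feature_aggregate(calls[[st]], imprinted, chunk = 15L)
  cbind(stage = st, rbind(fs$summary, fi$summary))
}))
write.table(feat, file.path(out_dir, "feature_aggregate.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nFeature-class means (PL):\n")
print(feat[feat$stage == "PL", c("class", "n_cpgs", "mean")], row.names = FALSE)

## replicate-style correlation: split each stage's bins odd/even as a
## stand-in for biological replicates of the same underlying state
cors <- vapply(stages, function(st) {
  bm <- bin_mean(calls[[st]], k = 100L)$mean_meth
  replicate_correlation(bm[seq(1, length(bm), 2)][seq_len(length(bm) %/% 2)],
                        bm[seq(2, length(bm), 2)][seq_len(length(bm) %/% 2)])
}, numeric(1))
write.table(data.frame(stage = stages, neighbor_bin_r = cors),
            file.path(out_dir, "bin_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## 5-kb coverage windows, normalized to the largest data set
frags <- lapply(stages, function(st)
  read.table(file.path(in_dir, sprintf("%s_fragments.tsv", st)), header = TRUE))
names(frags) <- stages
cw <- coverage_windows(frags, width = 5000L)
for (st in stages) {
  write.table(cw[[st]], file.path(out_dir, sprintf("%s_coverage5kb.tsv", st)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("\nWrote 100-kb traces, feature aggregates and normalized 5-kb coverage to", out_dir, "\n")
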