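#!/usr/bin/env Rscript
# Deterministic stand-in for an external CNN pose scorer. Implements the
# score-only contract: `Rscript mock_scorer.R -r receptor.pdb -l poses.sdf
# --score_only` prints one "CNNscore" and one "CNNaffinity" line per SDF
# record. Values are a stable hash of each pose's coordinates so reruns
# agree and distinct poses get distinct scores; they carry no physical
# meaning.

args <- commandArgs(trailingOnly = TRUE)
lig <- args[which(args == "-l") + 1]
if (length(lig) != 1 || !file.exists(lig)) {
  stop("usage: mock_scorer.R -r receptor.pdb -l poses.sdf --score_only")
}
lines <- readLines(lig, warn = FALSE)
ends <- grep("^\\$\\$\\$\\$", lines)
starts <- c(1, head(ends, -1) + 1)
for (k in seq_along(ends)) {
  block <- lines[starts[k]:ends[k]]
  h <- sum(utf8ToInt(paste(block, collapse = ""))) %% 9973
  cat(sprintf("Pose %d\n", k))
  cat(sprintf("CNNscore: %.4f\n", 0.3 + 0.6 * (h / 9973)))
  cat(sprintf("CNNaffinity: %.4f\n", 4 + 3 * ((h * 7) %% 9973) / 9973))
}
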