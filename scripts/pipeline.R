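#!/usr/bin/env Rscript
# Thin command-line wrapper over the stage runner:
#   Rscript scripts/pipeline.R <stage|all> [--config cfg.yaml]
#                              [--outdir dir] [--seed int]

suppressPackageStartupMessages(library(stepsel))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0L) {
  cat("usage: Rscript scripts/pipeline.R <simulate|screen|homerange|broadscale|ssf|autocorr|report|all>\n",
      "       [--config cfg.yaml] [--outdir dir] [--seed int]\n")
  quit(status = 1L)
}
stage <- args[1L]
arg_of <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
cfg_path <- arg_of("--config")
config <- if (is.null(cfg_path)) default_config() else read_run_config(cfg_path)
outdir <- arg_of("--outdir")
if (!is.null(outdir)) config$outdir <- outdir
seed <- arg_of("--seed")
if (!is.null(seed)) config$seed <- as.integer(seed)

if (stage == "all") run_study(config) else run_stage(stage, config)
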