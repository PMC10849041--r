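#!/usr/bin/env Rscript
# Thin command-line wrapper over striomap::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --config config.json --out outdir
#
# The JSON config must set `seed` and either a `simulate` block
# (cell_type + generation overrides) or `swc`/`puncta` (+ optional
# `sweeps`/`sweeps_meta`) input paths; see ?striomap::run_pipeline.

suppressPackageStartupMessages({
  library(optparse)
  library(striomap)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out", type = "character", default = "striomap_out")
)))
if (is.null(opt$config)) stop("--config is required")

run_pipeline(opt$config, opt$out)
cat("pipeline complete; outputs in ", opt$out, "\n", sep = "")
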