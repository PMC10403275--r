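#!/usr/bin/env Rscript

## Thin command-line wrapper over segconn::runPipeline.
##
## Usage:
##   Rscript scripts/netseg.R run-all <config.yaml>
##   Rscript scripts/netseg.R check <config.yaml>     # validate config only
##
## Exit codes: 0 ok, 2 config error, 3 data/stage error.

suppressPackageStartupMessages(library(segconn))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: netseg.R <run-all|check> <config.yaml>\n")
  quit(status = 2)
}
if (length(args) != 2 || !(args[1] %in% c("run-all", "check"))) usage()
if (!file.exists(args[2])) {
  message("config file not found: ", args[2])
  quit(status = 2)
}

config <- tryCatch(validateConfig(args[2]), error = function(e) {
  message("config error: ", conditionMessage(e))
  quit(status = 2)
})

if (args[1] == "check") {
  cat("config ok:", config$mode, "mode, seed", config$seed, "\n")
  quit(status = 0)
}

res <- tryCatch(runPipeline(config), error = function(e) {
  message("pipeline error: ", conditionMessage(e))
  quit(status = 3)
})
cat("pipeline complete:", config$out_dir, "\n")
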