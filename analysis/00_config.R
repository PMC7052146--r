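# Shared settings for the analysis drivers. Run each numbered script from
# the repository root; outputs accumulate under results/.
library(gbspopgen)

SEED <- 20260901L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

HYBRID_ID <- "HYB_01"
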