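#' Derive a stage seed from a master seed
#'
#' Pure function of (master seed, stage name): stages of a pipeline run are
#' independently reproducible. The result is a positive integer below 2^31.
#'
#' @param master_seed integer master seed
#' @param stage character stage name
#' @return integer seed
#' @export
derive_seed <- function(master_seed, stage) {
  h <- as.numeric(master_seed) %% 2147483647
  for (code in utf8ToInt(as.character(stage)))
    h <- (h * 131 + code) %% 2147483647
  as.integer(h + 1)
}
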