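# Bundled reference inputs.

#' Published expansion parameters for the Yarlung Tsangpo snow trout
#'
#' The published mismatch-distribution modes (tau) and expansion times
#' (T, Ma) for the six western populations of Schizothorax o'connori,
#' per marker: cytochrome b (mu = 1.0%/site/Myr, k = 1141 bp), control
#' region (mu = 3.6%/site/Myr, k = 714 bp) and their concatenation
#' (mu = 1.69%/site/Myr, k = 1855 bp); generation time 10 years.
#' Used as a worked input for [expansion_time].
#'
#' @return data frame with columns `population`, `marker`
#'   (cytb/cr/cytb_cr), `tau`, `T_ma`; attribute `marker_info` gives
#'   `mu_pct_per_myr` and `k` per marker.
#' @export
soconnori_tau_table <- function() {
  x <- read.csv(system.file("extdata", "soconnori_tau_table.csv",
                            package = "fishpopgen"),
                stringsAsFactors = FALSE)
  attr(x, "marker_info") <- data.frame(
    marker = c("cytb", "cr", "cytb_cr"),
    mu_pct_per_myr = c(1.0, 3.6, 1.69),
    k = c(1141, 714, 1855), stringsAsFactors = FALSE)
  x
}
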