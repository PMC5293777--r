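# Published group summaries shipped with the package. These are the printed
# group means (mean +/- SEM, n) from the source study's figures and tables:
# post-injection IOP per eye, intact transport per group, microbead:saline
# label and nuclear-localization ratios, retinal morphometry. They serve as
# inputs to worked-example reproduction (percent changes between printed
# means) and as calibration targets for the synthetic cohort defaults.

#' Published group summaries
#'
#' @return Data.frame with columns `quantity`, `marker`, `tissue`, `group`,
#'   `mean`, `sem`, `n`, `units`.
#' @export
published_group_summaries <- function() {
  f <- system.file("extdata", "published_group_summaries.csv",
                   package = "axoquant", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Look up one published group mean
#'
#' @param quantity,group Required selectors.
#' @param marker,tissue Optional selectors (use `NA` to match unset fields).
#' @return The published mean (single number).
#' @export
published_mean <- function(quantity, group, marker = NA, tissue = NA) {
  d <- published_group_summaries()
  sel <- d$quantity == quantity & d$group == group
  if (!is.na(marker)) sel <- sel & !is.na(d$marker) & d$marker == marker
  if (!is.na(tissue)) sel <- sel & !is.na(d$tissue) & d$tissue == tissue
  hit <- d[sel, , drop = FALSE]
  if (nrow(hit) != 1) {
    stopf("published_mean: %d matches for %s/%s/%s/%s",
          nrow(hit), quantity, group, marker, tissue)
  }
  hit$mean
}
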