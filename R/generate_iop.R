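# Tonometry time series for the unilateral microbead occlusion model: the
# microbead eye rises to baseline * (1 + elevation) from day 1 post-injection,
# the fellow saline eye stays at baseline. Day 0 is the injection day; days
# <= 0 are pre-injection and feed the baseline average.

#' Generate an IOP time series for one or more animals
#'
#' Defaults are calibrated to the microbead occlusion literature: baseline
#' near 20 mmHg and a ~30% unilateral elevation sustained for four weeks.
#' Each animal draws a subject-level baseline (between-animal sd
#' `animal_sd`); individual tonometry readings add measurement noise
#' (`measure_sd`).
#'
#' @param spec A [synthetic_spec()] (supplies the seed).
#' @param baseline_mmHg Population mean baseline IOP (> 0).
#' @param elevation_fraction Fractional elevation of the microbead eye from
#'   day 1 (>= 0; 0.30 is a typical bead-model magnitude).
#' @param n_days Post-injection days to simulate (>= 1).
#' @param n_pre_days Pre-injection monitoring days (2-3 expected).
#' @param animal_ids Character vector of animal identifiers.
#' @param animal_sd Between-animal sd of the subject baseline (mmHg).
#' @param measure_sd Tonometry measurement sd (mmHg).
#' @return A data.frame with columns `animal_id`, `eye`, `day`, `iop_mmHg`.
#'   Days run `-(n_pre_days - 1) ... 0` (pre-injection) then `1 ... n_days`.
#' @export
generate_iop_series <- function(spec, baseline_mmHg = 20.2,
                                elevation_fraction = 0.30, n_days = 28,
                                n_pre_days = 3, animal_ids = "A1",
                                animal_sd = 1.0, measure_sd = 1.5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (baseline_mmHg <= 0) stopf("`baseline_mmHg` must be > 0")
  if (elevation_fraction < 0) stopf("`elevation_fraction` must be >= 0")
  if (n_days < 1) stopf("`n_days` must be >= 1")
  if (n_pre_days < 1) stopf("`n_pre_days` must be >= 1")
  days <- c(seq.int(-(n_pre_days - 1), 0), seq_len(n_days))
  out <- vector("list", length(animal_ids))
  for (a in seq_along(animal_ids)) {
    mu_a <- with_seed(derive_seed(spec$seed, 600L + a),
                      stats::rnorm(1, baseline_mmHg, animal_sd))
    mean_for <- function(eye, day) {
      if (eye == "MICROBEAD" && day >= 1) mu_a * (1 + elevation_fraction) else mu_a
    }
    grid <- expand.grid(eye = EYES, day = days, stringsAsFactors = FALSE)
    mus <- mapply(mean_for, grid$eye, grid$day)
    vals <- with_seed(derive_seed(spec$seed, 700L + a),
                      stats::rnorm(nrow(grid), mus, measure_sd))
    out[[a]] <- data.frame(animal_id = animal_ids[a], eye = grid$eye,
                           day = grid$day, iop_mmHg = pmax(vals, 0.1))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
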