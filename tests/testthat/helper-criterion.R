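# Desk-scale world used by the pipeline-calibration checks: the reference
# 77-subject cohort, 40^3 phantoms with 12 small ellipsoid areas, histogram
# matching to subject 1, and the demo ranking profile. Model counts are
# scaled down for the test budget; the statistical structure of the
# protocol (partitioned hold-out, model averaging, median over partitions,
# random-feature null) is the full one.

criterion_phantom_spec <- function(signal = NULL) {
  phantom_spec(shape = c(40L, 40L, 40L), n_roi = 12L, signal = signal)
}

criterion_config <- function() ranking_config("demo")

# one all-noise replicate: returns the 12 per-area significance/relevance
# flags of the randomization test
run_noise_seed <- function(seed, n_replicates = 50) {
  co <- generate_cohort(cohort_spec(), seed = seed)
  feats <- extract_cohort(co, criterion_phantom_spec(), seed = seed)
  rk <- rank_areas(feats, co, "mf", criterion_config(), seed = seed)
  nf <- max(1L, as.integer(stats::median(rk$summary$n_selected)))
  nz <- noise_mae_distribution(co, "mf", criterion_config(),
    n_features = nf, n_replicates = n_replicates, seed = seed
  )
  area_significance(rk, nz)
}

# one planted-signal replicate: texture-contrast beta = 2 on area 1
run_planted_seed <- function(seed, n_replicates = 30) {
  sig <- tibble::tibble(
    roi_label = 1L, property = "texture-contrast",
    test = "mf", beta = 2
  )
  co <- generate_cohort(cohort_spec(), seed = seed)
  feats <- extract_cohort(co, criterion_phantom_spec(signal = sig),
    seed = seed
  )
  rk <- rank_areas(feats, co, "mf", criterion_config(), seed = seed)
  nf <- max(1L, as.integer(stats::median(rk$summary$n_selected)))
  nz <- noise_mae_distribution(co, "mf", criterion_config(),
    n_features = nf, n_replicates = n_replicates, seed = seed
  )
  sg <- area_significance(rk, nz)
  fb <- family_importance(rk$areas[["1"]])
  list(
    ranked_first = tidy(rk)$roi_label[1] == 1L,
    significant = sg$significant[sg$roi_label == 1L],
    family_share = stats::setNames(
      fb$family$share_pct,
      as.character(fb$family$family)
    )
  )
}
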