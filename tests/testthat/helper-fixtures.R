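# shared fixtures: small seeded cohorts and hand-built indicator matrices

small_generator <- function(n = 600, seed = 7, missing_rate_item = 0,
                            all_missing_fraction = 0, ...) {
  generator_config(
    n_episodes = n, seed = seed,
    missing_rate_item = missing_rate_item,
    all_missing_fraction = all_missing_fraction,
    ...
  )
}

separable_generator <- function(n = 600, k = 4, seed = 7, ...) {
  generator_config(
    n_episodes = n,
    cluster_proportions = rep(1 / k, k),
    indicator_profiles = separable_indicator_profiles(k),
    demographic_effects = list(),
    visit_rate_by_cluster = rep(4, k),
    all_missing_fraction = 0,
    seed = seed,
    ...
  )
}

true_labels_for <- function(cohort, m) {
  cohort$episodes$.true_cluster[
    match(m$episode_ids, cohort$episodes$episode_id)
  ]
}

# one visit per row; only the named measures present
toy_cohort <- function(visits, episode_ids = unique(visits$episode_id)) {
  blank <- tibble::tibble(
    episode_id = visits$episode_id,
    visit_number = stats::ave(seq_len(nrow(visits)), visits$episode_id,
                              FUN = seq_along),
    k10_total = NA_integer_, sofas = NA_integer_, mlt_total = NA_integer_,
    stage = NA_character_, diagnosis_code = NA_character_,
    presenting_issue = NA_character_, housing_issue_flag = NA_integer_,
    neet_flag = NA_integer_, benefits_flag = NA_integer_,
    trauma_flag = NA_integer_, cooccurring_flag = NA_integer_,
    aod_treatment_flag = NA_integer_
  )
  for (nm in setdiff(names(visits), "episode_id")) blank[[nm]] <- visits[[nm]]
  list(
    episodes = tibble::tibble(episode_id = episode_ids),
    visits = blank
  )
}

# simulate a 2x2 table by dichotomising a latent bivariate normal
simulate_tetra_table <- function(n, rho, margin_x = 0.5, margin_y = 0.5) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  x <- as.integer(z1 > qnorm(1 - margin_x))
  y <- as.integer(z2 > qnorm(1 - margin_y))
  table(factor(x, levels = 0:1), factor(y, levels = 0:1))
}
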