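#' Names of the 13 binary complexity indicators
#'
#' The fixed indicator order used throughout the package: three scale-based
#' indicators (psychological distress, quality of life, functioning), illness
#' stage, diagnosis, two presenting-issue indicators, and six visit-form
#' flags.
#'
#' @return character vector of length 13.
#' @export
complexity_indicator_names <- function() {
  c(
    "distress", "low_quality_of_life", "low_functioning", "later_stage",
    "severe_disorder", "self_harm_suicidality", "aod_treatment",
    "trauma_history", "housing_issues", "neet", "vocational_issue",
    "government_benefits", "cooccurring_difficulties"
  )
}

#' Cut-points used to dichotomise scale measures
#'
#' K10 total runs 10-50 and scores strictly above 30 indicate very high
#' psychological distress; SOFAS runs 0-100 and 60 or below indicates
#' moderate-to-severe functional impairment; MyLifeTracker runs 0-100
#' (higher = better quality of life) and has no published clinical cut, so
#' the low-quality-of-life threshold is a tunable parameter defaulting to
#' scores below 40; illness stage 2 or later counts as "later stage".
#'
#' @param mlt_low MLT scores strictly below this count as low quality of life.
#' @param stage_later minimum numeric stage counting as later illness stage.
#' @return named list with elements `k10_above`, `sofas_at_or_below`,
#'   `mlt_below`, `stage_at_or_above`.
#' @export
complexity_thresholds <- function(mlt_low = 40, stage_later = 2) {
  list(
    k10_above = 30,
    sofas_at_or_below = 60,
    mlt_below = mlt_low,
    stage_at_or_above = stage_later
  )
}

severe_diagnosis_codes <- function() {
  c("psychotic", "bipolar", "personality", "neurodevelopmental")
}

common_diagnosis_codes <- function() {
  c("anxiety", "depression", "adjustment", "other", "none")
}

stage_levels <- function() c("1a", "1b", "2", "3", "4")

presenting_issue_levels <- function() {
  c(
    "mental_health", "physical_health", "situational",
    "self_harm_suicidality", "education_employment", "other"
  )
}

#' Default within-cluster indicator probability profiles
#'
#' A stylised 4 x 13 matrix of Bernoulli probabilities describing the four
#' complexity phenotypes: a low-complexity majority; a distress phenotype
#' (very high distress, low quality of life, impaired functioning); a
#' psychosocial phenotype (similarly distressed but dominated by housing,
#' NEET, vocational and benefit issues); and a high-complexity phenotype
#' (later illness stage, severe disorders, trauma history and co-occurring
#' difficulties on top of clinical severity). The within-cluster
#' prevalences of the source study are not published, so these profiles are
#' a reconstruction from the qualitative cluster descriptions, with strong
#' contrasts (>= 0.5 probability gap) on each phenotype's defining
#' indicators.
#'
#' @param k number of clusters; only `k = 4` has a stylised default, other
#'   values get evenly spaced burden profiles for exercising k-selection.
#' @return k x 13 matrix with rows summing to each phenotype's expected
#'   indicator burden.
#' @export
default_indicator_profiles <- function(k = 4) {
  nm <- complexity_indicator_names()
  if (k == 4) {
    p <- rbind(
      low          = c(.10, .10, .15, .05, .02, .02, .01, .05, .02, .05, .05, .08, .05),
      distress     = c(.95, .90, .75, .10, .05, .08, .01, .12, .04, .08, .08, .10, .10),
      psychosocial = c(.90, .85, .40, .10, .05, .05, .04, .15, .60, .80, .80, .80, .20),
      high         = c(.75, .70, .90, .80, .65, .20, .10, .80, .25, .30, .30, .35, .80)
    )
  } else {
    # evenly spaced burden levels, alternating blocks so profiles separate
    p <- t(vapply(seq_len(k), function(i) {
      base <- 0.05 + 0.85 * (i - 1) / max(k - 1, 1)
      prob <- rep(0.05, 13)
      block <- ((seq_len(13) + i) %% k) == 0
      prob[block] <- 0.9
      prob[1:3] <- pmin(base + 0.05, 0.95)
      prob
    }, numeric(13)))
    rownames(p) <- paste0("cluster", seq_len(k))
  }
  colnames(p) <- nm
  p
}

#' Well-separated indicator profiles for recovery experiments
#'
#' Builds planted cluster profiles whose pairwise mean absolute probability
#' gap across all 13 indicators is at least `gap`: near-binary "codeword"
#' profiles (on-items at `p_hi`, off-items at `p_lo`) whose on-sets differ
#' in at least 8 of 13 positions for every pair. These are the planted
#' structures used by cluster-recovery and k-selection simulations, where
#' the question is whether the consensus machinery recovers a separable
#' truth — deliberately cleaner than the overlapping clinical phenotypes of
#' [default_indicator_profiles()].
#'
#' @param k number of clusters, 2 to 4.
#' @param gap required pairwise mean absolute probability gap.
#' @param p_lo,p_hi off- and on-item probabilities.
#' @return k x 13 probability matrix with strictly increasing row burdens.
#' @export
separable_indicator_profiles <- function(k = 4, gap = 0.5, p_lo = 0.05,
                                         p_hi = 0.95) {
  if (!k %in% 2:4) abort_config("separable profiles are defined for k in 2..4")
  words <- list(
    rep(0, 13),
    c(rep(1, 8), rep(0, 5)),
    c(rep(1, 4), rep(0, 4), rep(1, 5)),
    c(rep(0, 4), rep(1, 9))
  )
  # pairwise Hamming distances >= 8, so gaps of (p_hi - p_lo) * 8 / 13
  pick <- switch(as.character(k), "2" = c(1, 2), "3" = c(1, 2, 4),
                 "4" = 1:4)
  p <- do.call(rbind, lapply(words[pick], function(w) {
    ifelse(w == 1, p_hi, p_lo)
  }))
  # break burden ties so severity ordering is strict (row 3 slightly lighter)
  if (k == 4) p[3, p[3, ] == p_hi] <- p_hi - 0.02
  pg <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    mean(abs(p[i, ] - p[j, ]))
  }))
  stopifnot(all(pg[upper.tri(pg)] >= gap))
  colnames(p) <- complexity_indicator_names()
  rownames(p) <- paste0("cluster", seq_len(k))
  p
}

#' Default demographic effects on cluster membership
#'
#' Log relative-risk ratios applied on the multinomial-logit scale, per
#' predictor level (rows) and non-reference cluster (columns 2..K vs the
#' low-complexity reference). Magnitudes follow the regression findings the
#' package is designed to recover: gender-diverse young people carry log(3.41)
#' for the high-complexity cluster, Indigenous young people log(1.85) for the
#' psychosocial cluster, males reduced risk for the two moderate clusters,
#' CALD background protective, higher-IRSAD areas and greater remoteness
#' protective.
#'
#' @param k number of clusters; non-4 values return an empty list (no
#'   demographic tilting).
#' @return named list of matrices, one per predictor; each matrix has one row
#'   per non-reference level and `k - 1` columns.
#' @export
default_demographic_effects <- function(k = 4) {
  if (k != 4) return(list())
  eff <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("distress", "psychosocial", "high")
    m
  }
  list(
    gender = eff(
      male = c(-0.40, -0.30, 0.00),
      gender_diverse = c(0.60, 0.50, log(3.41))
    ),
    age_group = eff(
      `15-17` = c(0.20, 0.20, 0.20),
      `18-20` = c(0.30, 0.60, 0.30),
      `21-25` = c(0.30, 0.80, 0.40)
    ),
    indigenous = eff(yes = c(0.10, log(1.85), 0.30)),
    cald = eff(yes = c(-0.30, -0.30, -0.30)),
    irsad_tertile = eff(
      mid = c(-0.15, -0.25, -0.20),
      high = c(-0.30, -0.50, -0.40)
    ),
    remoteness = eff(
      inner_regional = c(0.00, 0.10, 0.00),
      outer_regional_remote = c(-0.20, -0.30, -0.30)
    )
  )
}

demographic_levels <- function() {
  list(
    gender = c("female", "male", "gender_diverse"),
    age_group = c("12-14", "15-17", "18-20", "21-25"),
    indigenous = c("no", "yes"),
    cald = c("no", "yes"),
    irsad_tertile = c("low", "mid", "high"),
    remoteness = c("major_city", "inner_regional", "outer_regional_remote")
  )
}

demographic_marginals <- function() {
  list(
    gender = c(female = 0.60, male = 0.36, gender_diverse = 0.04),
    age_group = c(`12-14` = 0.17, `15-17` = 0.35, `18-20` = 0.25, `21-25` = 0.23),
    indigenous = c(no = 0.91, yes = 0.09),
    cald = c(no = 0.86, yes = 0.14),
    irsad_tertile = c(low = 1 / 3, mid = 1 / 3, high = 1 / 3),
    remoteness = c(major_city = 0.55, inner_regional = 0.35,
                   outer_regional_remote = 0.10)
  )
}

#' Configuration for the synthetic episode-of-care generator
#'
#' Bundles every tunable of the synthetic minimum-data-set cohort: latent
#' cluster mixture, within-cluster indicator profiles, demographic effects on
#' membership, per-cluster visit intensity, item and episode-level
#' missingness, and the centre structure. Defaults emulate the published
#' cohort: cluster shares 39.8/19.9/21.8/18.5%, visit means 4.0/4.0/2.9/7.1,
#' a 14.1% all-indicators-missing stratum, and 113 service centres.
#'
#' @param n_episodes number of episodes of care to generate.
#' @param cluster_proportions probability vector over the K latent clusters
#'   (must sum to 1).
#' @param indicator_profiles K x 13 matrix of Bernoulli probabilities.
#' @param demographic_effects named list of log-RRR matrices (see
#'   [default_demographic_effects()]); empty list disables tilting.
#' @param visit_rate_by_cluster mean visits per episode, length K.
#' @param visit_dispersion negative-binomial size parameter for visit counts.
#' @param missing_rate_item per-episode, per-source-field missingness
#'   probability in `[0, 1)`.
#' @param all_missing_fraction share of episodes with every indicator source
#'   removed (the stratum excluded from analysis), in `[0, 1)`.
#' @param missing_mechanism `"MCAR"` or `"MAR"`; under MAR the item
#'   missingness odds are multiplied by `mar_odds` for episodes with
#'   `mar_covariate == mar_level`.
#' @param mar_covariate,mar_level,mar_odds MAR tilting: covariate column,
#'   level receiving tilted odds, and the odds multiplier.
#' @param n_centres number of service centres.
#' @param centre_mixing Dirichlet concentration for per-centre cluster
#'   prevalence (`Inf` = identical centres; smaller = more heterogeneity).
#' @param thresholds output of [complexity_thresholds()]; shared with the
#'   indicator mapping so planted states round-trip exactly.
#' @param seed integer master seed; the generator is a pure function of the
#'   config including this seed.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_episodes,
                             cluster_proportions = c(0.398, 0.199, 0.218, 0.185),
                             indicator_profiles = NULL,
                             demographic_effects = NULL,
                             visit_rate_by_cluster = c(4.0, 4.0, 2.9, 7.1),
                             visit_dispersion = 1.5,
                             missing_rate_item = 0,
                             all_missing_fraction = 0.141,
                             missing_mechanism = c("MCAR", "MAR"),
                             mar_covariate = "gender",
                             mar_level = "male",
                             mar_odds = 1,
                             n_centres = 113,
                             centre_mixing = 20,
                             thresholds = complexity_thresholds(),
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  k <- length(cluster_proportions)
  if (k < 1 || abs(sum(cluster_proportions) - 1) > 1e-12 ||
      any(cluster_proportions < 0)) {
    abort_config("cluster_proportions must be non-negative and sum to 1")
  }
  if (n_episodes < k) {
    abort_config("n_episodes (%d) must be at least the number of clusters (%d)",
                 n_episodes, k)
  }
  if (is.null(indicator_profiles)) indicator_profiles <- default_indicator_profiles(k)
  indicator_profiles <- as.matrix(indicator_profiles)
  if (nrow(indicator_profiles) != k || ncol(indicator_profiles) != 13) {
    abort_config("indicator_profiles must be %d x 13", k)
  }
  if (any(indicator_profiles < 0 | indicator_profiles > 1)) {
    abort_config("indicator_profiles entries must lie in [0, 1]")
  }
  if (is.null(demographic_effects)) demographic_effects <- default_demographic_effects(k)
  if (length(visit_rate_by_cluster) == 1) {
    visit_rate_by_cluster <- rep(visit_rate_by_cluster, k)
  }
  if (length(visit_rate_by_cluster) != k || any(visit_rate_by_cluster <= 0)) {
    abort_config("visit_rate_by_cluster must be %d positive means", k)
  }
  for (r in c(missing_rate_item, all_missing_fraction)) {
    if (r < 0 || r >= 1) abort_config("missingness rates must lie in [0, 1)")
  }
  if (n_centres < 1) abort_config("n_centres must be positive")
  structure(
    list(
      n_episodes = as.integer(n_episodes),
      k = k,
      cluster_proportions = cluster_proportions,
      indicator_profiles = indicator_profiles,
      demographic_effects = demographic_effects,
      visit_rate_by_cluster = visit_rate_by_cluster,
      visit_dispersion = visit_dispersion,
      missing_rate_item = missing_rate_item,
      all_missing_fraction = all_missing_fraction,
      missing_mechanism = missing_mechanism,
      mar_covariate = mar_covariate,
      mar_level = mar_level,
      mar_odds = mar_odds,
      n_centres = as.integer(n_centres),
      centre_mixing = centre_mixing,
      thresholds = thresholds,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# vectorised categorical sampler from a probability matrix (rows sum to 1)
sample_rows <- function(prob_matrix) {
  cp <- t(apply(prob_matrix, 1, cumsum))
  u <- runif(nrow(prob_matrix))
  as.integer(rowSums(u > cp) + 1L)
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha / sum(alpha) # degenerate guard
  g / sum(g)
}

#' Sample episode-level demographics and latent cluster labels
#'
#' The episode-level half of the generator: demographics from their
#' marginals, per-centre cluster prevalences from a Dirichlet around the
#' global mixture, and each episode's hidden cluster from a multinomial
#' logit combining the centre prevalence with the demographic log-RRR
#' effects. Useful on its own for regression simulations where visit-level
#' detail is not needed.
#'
#' @param config a [generator_config()].
#' @return tibble with one row per episode: ids, demographics, `n_visits`,
#'   hidden `.true_cluster` and the planted indicator states as a matrix
#'   attribute `planted`.
#' @export
sample_clusters <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_episodes
  k <- config$k
  seeds <- derive_seeds(config$seed, 3)

  with_seed(seeds[1], {
    marg <- demographic_marginals()
    demo <- lapply(marg, function(p) {
      names(p)[sample_rows(matrix(p, n, length(p), byrow = TRUE))]
    })
    demo <- tibble::as_tibble(demo)

    centre_id <- sample.int(config$n_centres, n, replace = TRUE)
    if (is.finite(config$centre_mixing)) {
      centre_prev <- t(vapply(
        seq_len(config$n_centres),
        function(i) rdirichlet_one(config$centre_mixing * config$cluster_proportions),
        numeric(k)
      ))
    } else {
      centre_prev <- matrix(config$cluster_proportions, config$n_centres, k,
                            byrow = TRUE)
    }

    # multinomial-logit tilt of the centre-level prevalence by demographics
    eta <- log(pmax(centre_prev[centre_id, , drop = FALSE], 1e-300))
    if (length(config$demographic_effects)) {
      for (nm in names(config$demographic_effects)) {
        effm <- config$demographic_effects[[nm]]
        lev <- demo[[nm]]
        for (row_lv in rownames(effm)) {
          hit <- lev == row_lv
          if (any(hit)) {
            eta[hit, -1] <- sweep(eta[hit, -1, drop = FALSE], 2,
                                  effm[row_lv, ], `+`)
          }
        }
      }
    }
    pm <- exp(eta - apply(eta, 1, max))
    pm <- pm / rowSums(pm)
    cluster <- sample_rows(pm)
  })

  with_seed(seeds[2], {
    planted <- matrix(
      runif(n * 13) < config$indicator_profiles[cluster, , drop = FALSE],
      n, 13
    )
    colnames(planted) <- complexity_indicator_names()
    mu <- pmax(config$visit_rate_by_cluster[cluster] - 1, 1e-8)
    n_visits <- 1L + stats::rnbinom(n, size = config$visit_dispersion, mu = mu)
    # two presenting-issue indicators share one field: need two visit slots
    need2 <- planted[, "self_harm_suicidality"] & planted[, "vocational_issue"]
    n_visits[need2] <- pmax(n_visits[need2], 2L)
  })

  out <- tibble::tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    episode_id = sprintf("E%06d", seq_len(n)),
    centre_id = sprintf("C%03d", centre_id)
  )
  out <- dplyr::bind_cols(out, demo)
  out$n_visits <- as.integer(n_visits)
  out$.true_cluster <- cluster
  attr(out, "planted") <- planted
  attr(out, "visit_seed") <- seeds[3]
  out
}

#' Generate a synthetic episode-of-care cohort
#'
#' Produces a full two-table cohort (episode-level demographics plus
#' visit-level clinical measures) with planted latent-cluster structure.
#' Continuous measures are drawn by inverse-threshold sampling: the binary
#' indicator state is drawn first from the cluster's profile, then the K10 /
#' SOFAS / MLT score is drawn uniformly from the matching side of its
#' cut-point at one randomly chosen "signal" visit, so that any-visit
#' dichotomisation reproduces the planted state exactly.
#'
#' @param config a [generator_config()].
#' @return object of class `eoc_cohort`: list with tibbles `episodes` and
#'   `visits`, and the generating `config`. The hidden labels live in
#'   `episodes$.true_cluster` and are never consumed by analysis stages.
#' @export
generate_cohort <- function(config) {
  ep <- sample_clusters(config)
  planted <- attr(ep, "planted")
  visit_seed <- attr(ep, "visit_seed")
  n <- nrow(ep)
  th <- config$thresholds

  visits <- with_seed(visit_seed, {
    idx <- rep.int(seq_len(n), ep$n_visits)
    visit_no <- sequence(ep$n_visits)
    nv <- ep$n_visits[idx]
    total <- length(idx)

    # one uniformly chosen signal visit per episode and scale indicator
    signal_pos <- function() {
      pos <- 1L + floor(runif(n) * ep$n_visits)
      pos[idx] == visit_no
    }
    draw_scale <- function(state, lo_hit, hi_hit, lo_miss, hi_miss, sig) {
      # "hit" side at the signal visit when planted, "miss" side elsewhere
      hit <- state[idx] & sig
      out <- integer(total)
      out[hit] <- sample(seq(lo_hit, hi_hit), sum(hit), replace = TRUE)
      out[!hit] <- sample(seq(lo_miss, hi_miss), sum(!hit), replace = TRUE)
      out
    }

    k10 <- draw_scale(planted[, "distress"],
                      th$k10_above + 1L, 50L, 10L, th$k10_above, signal_pos())
    sofas <- draw_scale(planted[, "low_functioning"],
                        0L, th$sofas_at_or_below, th$sofas_at_or_below + 1L,
                        100L, signal_pos())
    mlt <- draw_scale(planted[, "low_quality_of_life"],
                      0L, th$mlt_below - 1L, th$mlt_below, 100L, signal_pos())

    stage_later <- planted[ , "later_stage"]
    stage_ep <- character(n)
    stage_ep[stage_later] <- sample(c("2", "3", "4"), sum(stage_later),
                                    replace = TRUE, prob = c(.6, .3, .1))
    stage_ep[!stage_later] <- sample(c("1a", "1b"), sum(!stage_later),
                                     replace = TRUE)
    stage <- stage_ep[idx]

    sev <- planted[, "severe_disorder"]
    diag_sig <- signal_pos()
    diagnosis <- sample(common_diagnosis_codes(), total, replace = TRUE,
                        prob = c(.35, .35, .1, .1, .1))
    sev_hit <- sev[idx] & diag_sig
    diagnosis[sev_hit] <- sample(severe_diagnosis_codes(), sum(sev_hit),
                                 replace = TRUE)

    # presenting issue: self-harm and vocational signals get distinct visits
    sh <- planted[, "self_harm_suicidality"]
    vo <- planted[, "vocational_issue"]
    sh_pos <- 1L + floor(runif(n) * ep$n_visits)
    off <- 1L + floor(runif(n) * pmax(ep$n_visits - 1L, 1L))
    vo_pos <- ifelse(sh & vo, ((sh_pos - 1L + off) %% ep$n_visits) + 1L,
                     1L + floor(runif(n) * ep$n_visits))
    presenting <- sample(c("mental_health", "physical_health", "situational",
                           "other"), total, replace = TRUE,
                         prob = c(.7, .1, .15, .05))
    presenting[sh[idx] & sh_pos[idx] == visit_no] <- "self_harm_suicidality"
    presenting[vo[idx] & vo_pos[idx] == visit_no] <- "education_employment"

    flag_col <- function(ind_name) {
      state <- planted[, ind_name]
      sig <- signal_pos()
      as.integer(state[idx] & sig)
    }

    tibble::tibble(
      episode_id = ep$episode_id[idx],
      visit_number = visit_no,
      k10_total = k10,
      sofas = sofas,
      mlt_total = mlt,
      stage = stage,
      diagnosis_code = diagnosis,
      presenting_issue = presenting,
      housing_issue_flag = flag_col("housing_issues"),
      neet_flag = flag_col("neet"),
      benefits_flag = flag_col("government_benefits"),
      trauma_flag = flag_col("trauma_history"),
      cooccurring_flag = flag_col("cooccurring_difficulties"),
      aod_treatment_flag = flag_col("aod_treatment")
    )
  })

  attr(ep, "planted") <- NULL
  attr(ep, "visit_seed") <- NULL
  structure(
    list(episodes = ep, visits = visits, config = config,
         planted = planted),
    class = "eoc_cohort"
  )
}

#' @export
print.eoc_cohort <- function(x, ...) {
  cat(sprintf(
    "<eoc_cohort> %d episodes, %d visits, %d centres (seed %d)\n",
    nrow(x$episodes), nrow(x$visits),
    length(unique(x$episodes$centre_id)), x$config$seed
  ))
  invisible(x)
}

# columns of the visits table that feed each indicator source group
indicator_source_groups <- function() {
  list(
    k10 = "k10_total",
    mlt = "mlt_total",
    sofas = "sofas",
    stage = "stage",
    diagnosis = "diagnosis_code",
    presenting = "presenting_issue",
    housing = "housing_issue_flag",
    neet = "neet_flag",
    benefits = "benefits_flag",
    trauma = "trauma_flag",
    cooccurring = "cooccurring_flag",
    aod = "aod_treatment_flag"
  )
}

#' Remove indicator source fields to emulate minimum-data-set missingness
#'
#' Two layers: an `all_missing_fraction` share of episodes loses every
#' indicator source field (the stratum later removed by the exclusion
#' filter), and remaining episode-by-source cells are removed independently
#' at `missing_rate_item` (MCAR) or with odds multiplied by `mar_odds` for
#' episodes in the designated covariate level (MAR). Missingness is recorded
#' as `NA` in the visit fields; nothing is imputed here.
#'
#' @param cohort an `eoc_cohort`.
#' @param config the same [generator_config()] (carries the missingness
#'   settings and seed).
#' @return the cohort with `NA`-masked visit fields; episode table gains a
#'   logical `.all_missing` column.
#' @export
apply_missingness <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "eoc_cohort"))
  for (r in c(config$missing_rate_item, config$all_missing_fraction)) {
    if (r < 0 || r >= 1) abort_config("missingness rates must lie in [0, 1)")
  }
  n <- nrow(cohort$episodes)
  groups <- indicator_source_groups()
  seeds <- derive_seeds(config$seed + 7L, 1)

  with_seed(seeds[1], {
    all_missing <- runif(n) < config$all_missing_fraction
    p <- rep(config$missing_rate_item, n)
    if (config$missing_mechanism == "MAR" && config$mar_odds != 1 &&
        config$missing_rate_item > 0) {
      hit <- cohort$episodes[[config$mar_covariate]] == config$mar_level
      p[hit] <- plogis(qlogis(p[hit]) + log(config$mar_odds))
    }
    item_missing <- matrix(runif(n * length(groups)), n) < p
  })
  colnames(item_missing) <- names(groups)
  item_missing[all_missing, ] <- TRUE

  vis <- cohort$visits
  row_ep <- match(vis$episode_id, cohort$episodes$episode_id)
  for (g in names(groups)) {
    col <- groups[[g]]
    vis[[col]][item_missing[row_ep, g]] <- NA
  }
  cohort$visits <- vis
  cohort$episodes$.all_missing <- all_missing
  cohort
}

#' Write / read a cohort as delimited text plus a YAML config
#'
#' Persists the episode summary and per-visit tables as CSV and the full
#' generator configuration as YAML for provenance.
#'
#' @param cohort an `eoc_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` the paths invisibly; `read_cohort()` an
#'   `eoc_cohort` (without planted states, which are generation-time only).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    episodes = file.path(dir, "episodes.csv"),
    visits = file.path(dir, "visits.csv"),
    config = file.path(dir, "generator_config.yaml")
  )
  data.table::fwrite(cohort$episodes, paths$episodes)
  data.table::fwrite(cohort$visits, paths$visits)
  cfg <- cohort$config
  cfg$indicator_profiles <- apply(cfg$indicator_profiles, 1, as.list,
                                  simplify = FALSE)
  cfg$demographic_effects <- lapply(cfg$demographic_effects, function(m) {
    apply(m, 1, as.list, simplify = FALSE)
  })
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  episodes <- tibble::as_tibble(data.table::fread(
    file.path(dir, "episodes.csv"), colClasses = list(character = "centre_id"),
    na.strings = c("", "NA")
  ))
  visits <- tibble::as_tibble(data.table::fread(
    file.path(dir, "visits.csv"), colClasses = list(character = "stage"),
    na.strings = c("", "NA")
  ))
  cfg_path <- file.path(dir, "generator_config.yaml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  structure(list(episodes = episodes, visits = visits, config = config,
                 planted = NULL),
            class = "eoc_cohort")
}
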