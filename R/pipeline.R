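#' Configuration for an end-to-end pipeline run
#'
#' Bundles the generator (for synthetic runs) or an input cohort directory,
#' the indicator set, imputation and consensus settings, the regression
#' spec and the master seed. The chosen `k` may sit outside the diagnostic
#' range only as an explicit clinical override, which the manifest records.
#'
#' @param output_dir directory receiving every artefact.
#' @param generator a [generator_config()] for synthetic runs, or `NULL` to
#'   read a cohort from `input_dir`.
#' @param input_dir directory holding `episodes.csv` / `visits.csv` when no
#'   generator is given.
#' @param indicator_set list of indicator definitions.
#' @param m number of imputations.
#' @param k chosen cluster count.
#' @param k_range candidate k for diagnostics (`NULL` skips [select_k()]).
#' @param consensus_R,consensus_p consensus-clustering resamples and
#'   subsample fraction.
#' @param spec a [model_spec()].
#' @param save_consensus_matrix write the full consensus matrix (quadratic
#'   in n; default only when n <= 2000).
#' @param seed master seed for the whole run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            generator = NULL,
                            input_dir = NULL,
                            indicator_set = default_indicator_set(),
                            m = 20,
                            k = 4,
                            k_range = NULL,
                            consensus_R = 100,
                            consensus_p = 0.8,
                            spec = model_spec(),
                            save_consensus_matrix = NULL,
                            seed = 1L) {
  if (is.null(generator) && is.null(input_dir)) {
    abort_config("provide either a generator config or an input_dir")
  }
  if (!is.null(k_range) && !(k %in% k_range)) {
    message(sprintf(
      "chosen k = %d lies outside the diagnostic range; recorded as clinical override",
      k
    ))
  }
  structure(
    list(output_dir = output_dir, generator = generator,
         input_dir = input_dir, indicator_set = indicator_set,
         m = m, k = k, k_range = k_range,
         consensus_R = consensus_R, consensus_p = consensus_p,
         spec = spec, save_consensus_matrix = save_consensus_matrix,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the complexity pipeline end-to-end
#'
#' Sequences generate (optional) -> map -> filter -> impute -> cluster ->
#' network -> model -> report, writing every artefact plus a JSON manifest
#' of settings, seeds, stage list and file checksums. Re-running with the
#' same config reproduces byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with every in-memory result (`cohort`,
#'   `indicators`, `exclusion`, `imputations`, `consensus`, `diagnostics`,
#'   `network`, `model`, `accounting`, `characteristics`, `centres`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4)
  stages <- character(0)
  t_start <- Sys.time()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stages <<- c(stages, name)
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("generate", {
    if (!is.null(config$generator)) {
      co <- generate_cohort(config$generator)
      co <- apply_missingness(co, config$generator)
      write_cohort(co, file.path(out, "cohort"))
      co
    } else {
      read_cohort(config$input_dir)
    }
  })

  indicators <- stage("map", {
    ind <- derive_indicators(cohort, config$indicator_set)
    write_indicator_matrix(ind, file.path(out, "indicators.csv"))
    ind
  })

  excl <- stage("filter", {
    fl <- exclusion_filter(indicators)
    jsonlite::write_json(fl$report[c("n_total", "n_excluded", "n_retained")],
                         file.path(out, "exclusion_report.json"),
                         auto_unbox = TRUE, digits = NA)
    fl
  })

  imps <- stage("impute", {
    im <- impute_indicators(excl$matrix, m_count = config$m, seed = seeds[1])
    write_imputation_set(im, file.path(out, "imputations"))
    im
  })

  diagnostics <- NULL
  if (!is.null(config$k_range)) {
    diagnostics <- stage("diagnostics", {
      dg <- select_k(imps, config$k_range, R = config$consensus_R,
                     p = config$consensus_p, seed = seeds[2])
      jsonlite::write_json(
        list(diagnostics = dg$diagnostics, recommended_k = dg$recommended_k,
             chosen_k = config$k, no_structure = dg$no_structure,
             clinical_override = !(config$k == dg$recommended_k)),
        file.path(out, "k_diagnostics.json"), auto_unbox = TRUE, digits = NA
      )
      dg
    })
  }

  consensus <- stage("cluster", {
    n_ret <- length(excl$matrix$episode_ids)
    save_mat <- config$save_consensus_matrix %||% (n_ret <= 2000)
    cr <- consensus_kmeans(imps, config$k, R = config$consensus_R,
                           p = config$consensus_p, seed = seeds[3])
    write_consensus_result(cr, out, save_matrix = save_mat)
    cr
  })

  network <- stage("network", {
    nw <- pooled_tetrachoric(imps)
    write_tetra_network(nw, out)
    nw
  })

  retained <- match(excl$matrix$episode_ids, cohort$episodes$episode_id)
  covariates <- cohort$episodes[retained, ]

  model <- stage("model", {
    pm <- fit_pooled(covariates, consensus$labels, config$spec)
    write_pooled_model(pm, out)
    pm
  })

  report <- stage("report", {
    acc <- cohort_accounting(excl$report, consensus$labels)
    chars <- characteristics_by_cluster(cohort, excl$matrix,
                                        consensus$labels)
    centres <- centre_distribution(consensus$labels,
                                   covariates$centre_id)
    data.table::fwrite(acc$clusters, file.path(out, "cluster_accounting.csv"))
    data.table::fwrite(chars, file.path(out, "characteristics_by_cluster.csv"))
    data.table::fwrite(centres$prevalence, file.path(out, "centre_prevalence.csv"))
    data.table::fwrite(centres$density, file.path(out, "centre_density.csv"))
    jsonlite::write_json(acc$totals, file.path(out, "cohort_accounting.json"),
                         auto_unbox = TRUE, digits = NA)
    list(accounting = acc, characteristics = chars, centres = centres)
  })

  artefacts <- list.files(out, recursive = TRUE, full.names = TRUE)
  artefacts <- artefacts[!grepl("manifest\\.json$", artefacts)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("youthcomplexity")),
    seed = config$seed, stage_seeds = seeds, stages = stages,
    settings = list(m = config$m, k = config$k, k_range = config$k_range,
                    consensus_R = config$consensus_R,
                    consensus_p = config$consensus_p),
    recommended_k = if (!is.null(diagnostics)) diagnostics$recommended_k,
    chosen_k = config$k,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    artefacts = stats::setNames(
      as.list(unname(tools::md5sum(artefacts))),
      sub(paste0("^", out, "/?"), "", artefacts)
    )
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    cohort = cohort, indicators = indicators, exclusion = excl$report,
    imputations = imps, diagnostics = diagnostics, consensus = consensus,
    network = network, model = model,
    accounting = report$accounting, characteristics = report$characteristics,
    centres = report$centres, manifest = manifest
  ))
}

#' Rebuild report tables from cached pipeline artefacts
#'
#' Re-derives the accounting, characteristics and centre-distribution
#' tables from an existing run directory (cohort, indicator matrix,
#' exclusion report and cluster labels) without re-imputing or
#' re-clustering.
#'
#' @param output_dir directory of a completed [run_pipeline()] run.
#' @return invisible list with `accounting`, `characteristics`, `centres`.
#' @export
report_from_artifacts <- function(output_dir) {
  cohort <- read_cohort(file.path(output_dir, "cohort"))
  indicators <- read_indicator_matrix(file.path(output_dir, "indicators.csv"))
  report <- jsonlite::read_json(file.path(output_dir, "exclusion_report.json"),
                                simplifyVector = TRUE)
  lab <- data.table::fread(file.path(output_dir, "cluster_labels.csv"))
  keep <- match(lab$episode_id, indicators$episode_ids)
  retained <- new_indicator_matrix(
    indicators$episode_ids[keep],
    indicators$values[keep, , drop = FALSE],
    indicators$observed_mask[keep, , drop = FALSE],
    indicators$indicator_names
  )
  acc <- cohort_accounting(report, lab$cluster)
  chars <- characteristics_by_cluster(cohort, retained, lab$cluster)
  centres <- centre_distribution(
    lab$cluster,
    cohort$episodes$centre_id[match(lab$episode_id,
                                    cohort$episodes$episode_id)]
  )
  data.table::fwrite(acc$clusters, file.path(output_dir, "cluster_accounting.csv"))
  data.table::fwrite(chars, file.path(output_dir, "characteristics_by_cluster.csv"))
  data.table::fwrite(centres$prevalence, file.path(output_dir, "centre_prevalence.csv"))
  data.table::fwrite(centres$density, file.path(output_dir, "centre_density.csv"))
  jsonlite::write_json(acc$totals, file.path(output_dir, "cohort_accounting.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(accounting = acc, characteristics = chars, centres = centres))
}

#' Cohort accounting: exclusions and cluster shares
#'
#' Rebuilds the episode bookkeeping from integer counts: total, excluded
#' and retained episodes (conserving `total = excluded + retained`) and
#' per-cluster counts with percentages of the retained sample. Percentages
#' are computed from counts and rendered half-up to one decimal.
#'
#' @param filter_report report element of [exclusion_filter()] (or any list
#'   with `n_total`, `n_excluded`, `n_retained`).
#' @param labels cluster labels of the retained episodes.
#' @return list with `totals` (n_total, n_excluded, n_retained,
#'   pct_excluded) and `clusters` tibble (cluster, n, pct).
#' @export
cohort_accounting <- function(filter_report, labels) {
  nt <- filter_report$n_total
  nx <- filter_report$n_excluded
  nr <- filter_report$n_retained
  stopifnot(nt == nx + nr, length(labels) == nr)
  k <- max(labels)
  counts <- tabulate(labels, k)
  stopifnot(sum(counts) == nr)
  list(
    totals = list(
      n_total = nt, n_excluded = nx, n_retained = nr,
      pct_excluded = round_half_up(100 * nx / nt, 1)
    ),
    clusters = tibble::tibble(
      cluster = seq_len(k),
      n = counts,
      pct = round_half_up(100 * counts / nr, 1)
    )
  )
}

#' Characteristics of episodes by cluster
#'
#' Per cluster: size, demographic composition, visit statistics and the
#' mean indicator count, with missing indicators treated as not reporting
#' the factor (counted as 0).
#'
#' @param cohort the `eoc_cohort`.
#' @param indicators the retained `indicator_matrix` (pre-imputation; its
#'   missing cells count as 0 in the indicator burden).
#' @param labels cluster labels aligned with `indicators$episode_ids`.
#' @return tibble, one row per cluster.
#' @export
characteristics_by_cluster <- function(cohort, indicators, labels) {
  stopifnot(length(labels) == length(indicators$episode_ids))
  rows <- match(indicators$episode_ids, cohort$episodes$episode_id)
  ep <- cohort$episodes[rows, ]
  burden <- rowSums(indicators$values == 1L, na.rm = TRUE)

  df <- tibble::tibble(
    cluster = labels,
    n_visits = ep$n_visits,
    burden = burden,
    gender = ep$gender,
    age_group = ep$age_group,
    indigenous = ep$indigenous
  )
  df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct = NA_real_,
      mean_visits = mean(.data$n_visits),
      median_visits = stats::median(.data$n_visits),
      mean_indicator_count = mean(.data$burden),
      pct_female = round_half_up(100 * mean(.data$gender == "female"), 1),
      pct_male = round_half_up(100 * mean(.data$gender == "male"), 1),
      pct_gender_diverse =
        round_half_up(100 * mean(.data$gender == "gender_diverse"), 1),
      pct_indigenous = round_half_up(100 * mean(.data$indigenous == "yes"), 1),
      pct_under_18 =
        round_half_up(100 * mean(.data$age_group %in% c("12-14", "15-17")), 1),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1))
}

#' Cluster prevalence across service centres
#'
#' Per-centre cluster prevalences with their ranges and Gaussian
#' kernel-density curves (Silverman bandwidth) for the smoothed-distribution
#' figure; exported as plot-ready points rather than an image. Centres with
#' fewer than 20 episodes are flagged `low_n` but retained.
#'
#' @param labels cluster labels.
#' @param centre_ids centre identifier per episode (>= 2 distinct centres).
#' @param density_points number of density-curve points per cluster.
#' @return list with `prevalence` (centre x cluster tibble), `ranges`
#'   (min/max prevalence per cluster) and `density` (curve points).
#' @export
centre_distribution <- function(labels, centre_ids, density_points = 128) {
  stopifnot(length(labels) == length(centre_ids))
  if (length(unique(centre_ids)) < 2) {
    abort_config("centre_distribution needs at least 2 centres")
  }
  k <- max(labels)
  tab <- table(centre_ids, factor(labels, levels = seq_len(k)))
  sizes <- rowSums(tab)
  prev <- sweep(unclass(tab), 1, sizes, `/`)
  prevalence <- tibble::tibble(
    centre_id = rep(rownames(tab), k),
    cluster = rep(seq_len(k), each = nrow(tab)),
    n_episodes = rep(as.integer(sizes), k),
    prevalence = as.vector(prev),
    low_n = rep(sizes < 20, k)
  )
  ranges <- prevalence |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(min = min(.data$prevalence), max = max(.data$prevalence),
                     .groups = "drop")
  density <- dplyr::bind_rows(lapply(seq_len(k), function(cl) {
    x <- prev[, cl]
    if (length(unique(x)) < 2) {
      return(tibble::tibble(cluster = cl, prevalence = unique(x), density = Inf))
    }
    d <- stats::density(x, bw = "nrd0", n = density_points, from = 0, to = 1)
    tibble::tibble(cluster = cl, prevalence = d$x, density = d$y)
  }))
  list(prevalence = prevalence, ranges = ranges, density = density)
}
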