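#' Fit combination models to a classified neural population
#'
#' Reproduces the neural modeling sequence: (1) gated power law on the
#' binocular gate neurons, (2) power law of the dominant-eye rate on the
#' true binocular neurons, (3) a single-exponent Minkowski fit on the true
#' binocular neurons, and (4) a power law on the combined facilitatory
#' population. The Minkowski model is never fit to gate neurons (they lack
#' a reliable second monocular response) or to the combined population for
#' the same reason.
#'
#' @param records Neuron table (see [generate_neural_population()] or
#'   [read_neural_csv()] for the schema). Classified with
#'   [classify_neurons()] if a `class` column is absent.
#' @param tol Classification tolerance when classification is needed.
#' @return A tibble with one row per dataset/model: columns `dataset`,
#'   `model`, `n_obs`, `a`, `se_a`, `n`, `se_n`, `m`, `se_m`, `r2`, `note`.
#'   Subtypes with fewer than 3 members yield a row flagged
#'   `note = "insufficient"` with missing estimates.
#' @export
run_neural_analysis <- function(records, tol = 0.05) {
  if (!("class" %in% names(records))) records <- classify_neurons(records, tol = tol)
  gate <- records[records$class == "gate_facilitatory", ]
  true <- records[records$class == "true_facilitatory", ]
  facil <- rbind(gate, true)

  power_row <- function(dataset, dat) {
    if (nrow(dat) < 3) {
      return(summary_row(dataset, "power_law", nrow(dat), note = "insufficient"))
    }
    f <- fit_power_law(dat$rate_dom, dat$rate_binoc)
    summary_row(dataset, "power_law", f$n_obs, a = f$a, se_a = f$se_a,
                n = f$n, se_n = f$se_n, r2 = f$r2)
  }
  mink_row <- function(dataset, dat) {
    if (nrow(dat) < 3) {
      return(summary_row(dataset, "minkowski", nrow(dat), note = "insufficient"))
    }
    f <- fit_minkowski_global(dat$rate_dom, dat$rate_nondom, dat$rate_binoc)
    summary_row(dataset, "minkowski", f$n_obs, m = f$m, se_m = f$se_m,
                r2 = f$r2)
  }

  dplyr::bind_rows(
    power_row("gate_neurons", gate),
    power_row("true_binocular_neurons", true),
    mink_row("true_binocular_neurons", true),
    power_row("combined_facilitatory_neurons", facil)
  )
}

summary_row <- function(dataset, model, n_obs, a = NA_real_, se_a = NA_real_,
                        n = NA_real_, se_n = NA_real_, m = NA_real_,
                        se_m = NA_real_, r2 = NA_real_, note = "") {
  tibble::tibble(dataset = dataset, model = model, n_obs = n_obs, a = a,
                 se_a = se_a, n = n, se_n = se_n, m = m, se_m = se_m,
                 r2 = r2, note = note)
}

#' Model binocular contrast sensitivity across studies
#'
#' The psychophysical analysis: subjects are screened for binocular
#' enhancement at a majority of spatial frequencies, sensitivities are split
#' into better and worse eye per row, and included subjects are averaged
#' within each study at each spatial frequency. The pooled (study x
#' frequency) means are then fit with the gated power law (binocular vs
#' best-eye sensitivity) and with a single-exponent Minkowski model, and the
#' Minkowski exponent is additionally estimated per spatial frequency in
#' three ways: the mean of per-subject root-found exponents (invalid and
#' extreme triples excluded), a least-squares fit across subjects at that
#' frequency, and root-finding on the across-subject averaged sensitivities.
#'
#' @param records CSF table (see [generate_csf_dataset()] or
#'   [read_csf_csv()] for the schema).
#' @param exclude_nonenhancing_rows_from_lsq Should rows without
#'   enhancement at a frequency also be dropped from the per-frequency
#'   least-squares estimate (default `FALSE`; they are always dropped from
#'   the root-finding estimates, where no valid exponent exists)?
#' @return A list with elements `summary` (pooled-fit rows in the shape of
#'   [run_neural_analysis()]), `means` (per study x frequency mean best,
#'   worst and binocular sensitivity with the number of included subjects),
#'   `per_sf_m` (tibble of the three per-frequency exponent estimates), and
#'   `screen` (the per-subject screening table).
#' @export
run_psychophysics_analysis <- function(records,
                                       exclude_nonenhancing_rows_from_lsq =
                                         FALSE) {
  screen <- subject_enhancement_screen(records)
  keep <- screen[screen$include, c("study", "subject")]
  dat <- dplyr::inner_join(tibble::as_tibble(records), keep,
                           by = c("study", "subject"))
  if (nrow(dat) == 0) {
    stop("run_psychophysics_analysis(): no subject passes the enhancement screen",
         call. = FALSE)
  }
  dat <- best_worst_split(dat)
  dat <- enhancement_flags(dat)

  means <- dplyr::summarise(
    dplyr::group_by(dat, .data$study, .data$sf),
    best = mean(.data$sens_best), worst = mean(.data$sens_worst),
    binoc = mean(.data$sens_binoc), n_subjects = dplyr::n(),
    .groups = "drop"
  )

  pl <- fit_power_law(means$best, means$binoc)
  mk <- fit_minkowski_global(means$best, means$worst, means$binoc)
  summary <- dplyr::bind_rows(
    summary_row("pooled_csf_means", "power_law", pl$n_obs, a = pl$a,
                se_a = pl$se_a, n = pl$n, se_n = pl$se_n, r2 = pl$r2),
    summary_row("pooled_csf_means", "minkowski", mk$n_obs, m = mk$m,
                se_m = mk$se_m, r2 = mk$r2)
  )

  per_sf <- lapply(sort(unique(dat$sf)), function(f) {
    sub <- dat[dat$sf == f, ]
    enh <- sub[sub$enhancing, ]
    # method 1: mean of per-subject root-found exponents
    m_subj <- NA_real_; n_valid <- 0L
    if (nrow(enh) > 0) {
      sol <- solve_minkowski_exponent(enh$sens_best, enh$sens_worst,
                                      enh$sens_binoc)
      ok <- sol$status == "ok"
      n_valid <- sum(ok)
      if (n_valid > 0) m_subj <- mean(sol$m[ok])
    }
    # method 2: least-squares fit across subjects at this frequency
    lsq_dat <- if (exclude_nonenhancing_rows_from_lsq) enh else sub
    m_lsq <- NA_real_
    if (nrow(lsq_dat) >= 2 &&
        any(lsq_dat$sens_binoc > lsq_dat$sens_best)) {
      m_lsq <- tryCatch(
        fit_minkowski_global(lsq_dat$sens_best, lsq_dat$sens_worst,
                             lsq_dat$sens_binoc)$m,
        error = function(e) NA_real_
      )
    }
    # method 3: root-finding on across-subject averaged data
    avg <- solve_minkowski_exponent(mean(sub$sens_best), mean(sub$sens_worst),
                                    mean(sub$sens_binoc))
    tibble::tibble(sf = f, m_subject_mean = m_subj, n_valid = n_valid,
                   m_lsq = m_lsq, m_avg_data = avg$m,
                   avg_status = avg$status)
  })

  list(summary = summary, means = means,
       per_sf_m = dplyr::bind_rows(per_sf), screen = screen)
}

#' Compare weighted-average models on the Between neurons
#'
#' Evaluates the two fully constrained weighted-average rules -- the
#' magnitude-weighted (Schroedinger) average and the inverse-variance (MLE)
#' average -- against the observed binocular rates of the mildly suppressive
#' "Between" neurons. For each model it reports the Pearson correlation
#' between predicted and observed rates, the proportionality constant (the
#' slope of the zero-intercept regression of observed on predicted, i.e.
#' the multiplicative compensation that would align the model with the
#' data), and the mean predicted/observed ratio.
#'
#' @param records Neuron table; restricted internally to the
#'   [macleod_between_filter()] subset.
#' @param tol Classification tolerance.
#' @return A tibble with one row per model: `model`, `n_obs`,
#'   `correlation`, `proportionality`, `mean_ratio`.
#' @export
compare_suppressive_models <- function(records, tol = 0.05) {
  between <- macleod_between_filter(records, tol = tol)
  if (nrow(between) < 3) {
    stop("compare_suppressive_models(): fewer than 3 Between neurons",
         call. = FALSE)
  }
  if (!all(c("var_dom", "var_nondom") %in% names(between))) {
    stop("compare_suppressive_models(): variance columns are required for MLE",
         call. = FALSE)
  }
  obs <- between$rate_binoc
  preds <- list(
    schrodinger = schrodinger_combine(between$rate_dom,
                                      between$rate_nondom)$predicted,
    mle = mle_combine(between$rate_dom, between$rate_nondom,
                      between$var_dom, between$var_nondom)$predicted
  )
  dplyr::bind_rows(lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    tibble::tibble(
      model = nm, n_obs = length(obs),
      correlation = stats::cor(p, obs),
      proportionality = sum(obs * p) / sum(p^2),
      mean_ratio = mean(p / obs)
    )
  }))
}

#' Minkowski exponent as a function of spatial frequency
#'
#' The averaged-data estimate: screened subjects' best, worst and binocular
#' sensitivities are averaged at each spatial frequency and a single
#' exponent is root-found from each averaged triple. Frequencies whose
#' averaged binocular sensitivity does not exceed the averaged best eye get
#' a missing entry rather than an error.
#'
#' @param records CSF table.
#' @return A tibble with columns `sf`, `m`, `status`.
#' @export
minkowski_vs_sf <- function(records) {
  screen <- subject_enhancement_screen(records)
  keep <- screen[screen$include, c("study", "subject")]
  dat <- dplyr::inner_join(tibble::as_tibble(records), keep,
                           by = c("study", "subject"))
  # when nobody passes the screen, report per-frequency validity on the
  # full sample instead of failing (the triples are no_solution anyway)
  if (nrow(dat) == 0) dat <- tibble::as_tibble(records)
  dat <- best_worst_split(dat)
  avg <- dplyr::summarise(
    dplyr::group_by(dat, .data$sf),
    best = mean(.data$sens_best), worst = mean(.data$sens_worst),
    binoc = mean(.data$sens_binoc), .groups = "drop"
  )
  sol <- solve_minkowski_exponent(avg$best, avg$worst, avg$binoc)
  tibble::tibble(sf = avg$sf, m = sol$m, status = sol$status)
}
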