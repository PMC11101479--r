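#' Configuration for the synthetic binocular datasets
#'
#' Bundles every knob of the neural and psychophysical generators into a
#' validated list. The defaults emulate the study conditions the analysis is
#' designed for: a single-unit population of 10 binocular gate neurons, 55
#' true binocular neurons and 48 suppressive neurons (35 of them "Between"),
#' and three contrast-sensitivity studies of 9, 25 and 45 subjects measured
#' at 6, 6 and 5 spatial frequencies respectively, with 5 non-enhancing
#' subjects placed in the 25-subject study.
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_gate,n_true,n_suppressive Neural subtype counts (defaults 10, 55,
#'   48).
#' @param n_between How many of the suppressive neurons are "Between"
#'   neurons (default 35); the rest are strongly suppressive.
#' @param generator_neural Rule generating facilitatory binocular rates:
#'   `"power_law"` (default), `"minkowski"`, or `"schrodinger"`.
#' @param gate_params,true_params Named vectors `c(a=, n=)` for the gated and
#'   true-binocular power laws (defaults `a=2.2, n=0.84` and `a=2.14,
#'   n=0.89`).
#' @param neural_m Minkowski exponent used when `generator_neural =
#'   "minkowski"` (default 1.71).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied to generated binocular responses (default 0.15; 0 gives
#'   noiseless data that satisfy the generating equation exactly).
#' @param variance_model `"poisson_like"` (variance = mean; default) or
#'   `"constant_cv"` (variance = (cv * mean)^2); either way firing-rate
#'   variance grows with firing-rate magnitude.
#' @param rate_range Dominant-eye firing-rate span, drawn log-uniformly
#'   (default `c(5, 300)` spikes/s, a two-decade range).
#' @param nondom_ratio_shape Beta shape parameters for the non-dominant /
#'   dominant rate ratio of binocularly driven neurons (default
#'   `c(4, 2.5)`, mean ratio about 0.6).
#' @param studies Data frame with columns `study`, `n_subjects`, `peak_sens`
#'   and a list-column `sf` of spatial-frequency grids. The default three
#'   studies share the grid 1, 1.5, 3, 6, 12, 18.5 c/deg (the third drops to
#'   five frequencies, 1.5-18 c/deg) and differ in overall sensitivity so
#'   the pooled data span well over 1.5 decades.
#' @param generator_csf `"power_law"` (default) or `"minkowski"` rule for
#'   binocular sensitivity of enhancing subjects.
#' @param csf_params Named vector `c(a=, n=)` for the psychophysical power
#'   law (default `a=1.63, n=0.93`).
#' @param csf_m Minkowski exponent for `generator_csf = "minkowski"`; a
#'   scalar, or a vector along the spatial-frequency grid to generate a
#'   frequency-dependent exponent (default 2.65).
#' @param csf_peak_sf,csf_bw Peak (c/deg) and half-width (decades of
#'   frequency) of the log-parabola mean sensitivity curve (defaults 3 and
#'   0.8).
#' @param subject_sd Log-scale SD of the per-subject sensitivity level
#'   (default 0.15).
#' @param interocular_ratio_sd Log-scale SD of the right/left sensitivity
#'   ratio (default 0.2), drawn per subject per frequency so the better eye
#'   can switch across frequencies.
#' @param n_nonenhancers Subjects generated without binocular enhancement
#'   (default 5), placed in `nonenhancer_study` (default the second study).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_gate = 10L, n_true = 55L,
                             n_suppressive = 48L, n_between = 35L,
                             generator_neural = c("power_law", "minkowski",
                                                  "schrodinger"),
                             gate_params = c(a = 2.2, n = 0.84),
                             true_params = c(a = 2.14, n = 0.89),
                             neural_m = 1.71,
                             noise_cv = 0.15,
                             variance_model = c("poisson_like", "constant_cv"),
                             rate_range = c(5, 300),
                             nondom_ratio_shape = c(4, 2.5),
                             studies = default_studies(),
                             generator_csf = c("power_law", "minkowski"),
                             csf_params = c(a = 1.63, n = 0.93),
                             csf_m = 2.65,
                             csf_peak_sf = 3, csf_bw = 0.8,
                             subject_sd = 0.15,
                             interocular_ratio_sd = 0.2,
                             n_nonenhancers = 5L,
                             nonenhancer_study = 2L) {
  generator_neural <- match.arg(generator_neural)
  variance_model <- match.arg(variance_model)
  generator_csf <- match.arg(generator_csf)
  counts <- c(n_gate = n_gate, n_true = n_true, n_suppressive = n_suppressive,
              n_between = n_between, n_nonenhancers = n_nonenhancers)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (n_between > n_suppressive) {
    stop("n_between cannot exceed n_suppressive", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(studies),
            all(c("study", "n_subjects", "peak_sens", "sf") %in% names(studies)))
  if (n_nonenhancers > 0 &&
      n_nonenhancers > studies$n_subjects[nonenhancer_study]) {
    stop("n_nonenhancers exceeds the chosen study's subject count",
         call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_gate = as.integer(n_gate),
              n_true = as.integer(n_true),
              n_suppressive = as.integer(n_suppressive),
              n_between = as.integer(n_between),
              generator_neural = generator_neural,
              gate_params = gate_params, true_params = true_params,
              neural_m = neural_m, noise_cv = noise_cv,
              variance_model = variance_model, rate_range = rate_range,
              nondom_ratio_shape = nondom_ratio_shape,
              studies = studies, generator_csf = generator_csf,
              csf_params = csf_params, csf_m = csf_m,
              csf_peak_sf = csf_peak_sf, csf_bw = csf_bw,
              subject_sd = subject_sd,
              interocular_ratio_sd = interocular_ratio_sd,
              n_nonenhancers = as.integer(n_nonenhancers),
              nonenhancer_study = as.integer(nonenhancer_study))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default three-study design for synthetic contrast sensitivity
#'
#' Three studies of 9, 25 and 45 subjects. The first two use the six
#' centroid spatial frequencies 1, 1.5, 3, 6, 12, 18.5 c/deg; the third uses
#' five frequencies spanning 1.5-18 c/deg. Peak sensitivities differ across
#' studies (180, 45, 110) so that the pooled best-eye sensitivities cover
#' the wide range a stable power-law fit needs.
#'
#' @return A tibble with columns `study`, `n_subjects`, `peak_sens` and the
#'   list-column `sf`.
#' @export
default_studies <- function() {
  tibble::tibble(
    study = c("studyA", "studyB", "studyC"),
    n_subjects = c(9L, 25L, 45L),
    peak_sens = c(180, 45, 110),
    sf = list(c(1, 1.5, 3, 6, 12, 18.5),
              c(1, 1.5, 3, 6, 12, 18.5),
              c(1.5, 3, 6, 12, 18))
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic binocular-data configuration\n")
  cat(sprintf("  seed %d | neurons: %d gate + %d true + %d suppressive (%d between)\n",
              x$seed, x$n_gate, x$n_true, x$n_suppressive, x$n_between))
  cat(sprintf("  neural generator: %s | noise CV %.2f | variance: %s\n",
              x$generator_neural, x$noise_cv, x$variance_model))
  cat(sprintf("  CSF: %d studies, %d subjects total, generator %s\n",
              nrow(x$studies), sum(x$studies$n_subjects), x$generator_csf))
  invisible(x)
}

# Multiplicative lognormal noise with mean 1 and the requested CV.
lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

# Redraw noise until `accept(value)` holds for every element (vectorized
# rejection with an iteration cap; at cv = 0 the deterministic value is
# returned untouched so noiseless closure is exact).
draw_conditioned <- function(base, cv, accept, max_iter = 2000) {
  val <- base * lognoise(length(base), cv)
  if (cv == 0) return(val)
  bad <- !accept(val)
  it <- 0
  while (any(bad) && it < max_iter) {
    val[bad] <- base[bad] * lognoise(sum(bad), cv)
    bad <- !accept(val)
    it <- it + 1
  }
  val
}

#' Generate a synthetic binocular single-unit population
#'
#' Emulates the statistical structure of a V1 binocular firing-rate dataset.
#' Dominant-eye rates are drawn log-uniformly over two decades; non-dominant
#' rates are a Beta-distributed fraction of the dominant rate for
#' binocularly driven neurons and near zero for gate neurons. Binocular
#' rates follow the configured combination rule -- gated power law for
#' facilitatory neurons (or Minkowski/Schroedinger variants), the
#' magnitude-weighted average for Between neurons, and a fraction of the
#' non-dominant rate for strongly suppressive neurons -- times multiplicative
#' lognormal noise with CV `noise_cv`. As with real single-unit populations,
#' whose suppressive subtypes are defined directly by where the measured
#' binocular rate falls, noisy suppressive draws are conditioned on the
#' record matching its subtype (Between: binocular between the monocular
#' rates; suppressive-other: binocular below the non-dominant rate);
#' facilitatory draws are left unconditioned, so a boundary record can fall
#' below its dominant rate at high rates where enhancement is weakest. At
#' `noise_cv = 0` every record satisfies its generating equation exactly.
#' Firing-rate variances are assigned by the variance model so that variance
#' grows with rate magnitude.
#'
#' The generating subtype is attached as a `truth_label` column that no
#' analysis stage reads; it exists so that recovery can be scored without
#' leakage.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `id`, `rate_dom`, `rate_nondom`,
#'   `rate_binoc`, `var_dom`, `var_nondom`, `responsive_nondom`,
#'   `truth_label`.
#' @export
generate_neural_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cv <- config$noise_cv
  lo <- log(config$rate_range[1]); hi <- log(config$rate_range[2])
  sh <- config$nondom_ratio_shape

  facil_binoc <- function(dom, nondom, params) {
    base <- switch(config$generator_neural,
      power_law = power_law_amplify(dom, params["a"], params["n"]),
      minkowski = minkowski_combine(dom, nondom, config$neural_m),
      schrodinger = schrodinger_combine(dom, nondom)$predicted
    )
    base * lognoise(length(base), cv)
  }

  # gate neurons: driven by one eye, non-dominant rate near zero
  n_g <- config$n_gate
  dom_g <- exp(stats::runif(n_g, lo, hi))
  nondom_g <- stats::runif(n_g) * pmin(2, 0.08 * dom_g)
  binoc_g <- if (n_g > 0) {
    base <- power_law_amplify(dom_g, config$gate_params["a"],
                              config$gate_params["n"])
    base * lognoise(n_g, cv)
  } else numeric(0)

  # true binocular facilitatory neurons
  n_t <- config$n_true
  dom_t <- exp(stats::runif(n_t, lo, hi))
  nondom_t <- dom_t * stats::rbeta(n_t, sh[1], sh[2])
  binoc_t <- if (n_t > 0) {
    facil_binoc(dom_t, nondom_t, config$true_params)
  } else numeric(0)

  # suppressive neurons: n_between magnitude-weighted averagers, the rest
  # firing below even the non-dominant eye
  n_b <- config$n_between
  n_o <- config$n_suppressive - n_b
  dom_b <- exp(stats::runif(n_b, lo, hi))
  nondom_b <- dom_b * stats::rbeta(n_b, sh[1], sh[2])
  binoc_b <- if (n_b > 0) {
    base <- schrodinger_combine(dom_b, nondom_b)$predicted
    draw_conditioned(base, cv, function(v) v >= nondom_b & v <= dom_b)
  } else numeric(0)
  dom_o <- exp(stats::runif(n_o, lo, hi))
  nondom_o <- dom_o * stats::rbeta(n_o, sh[1], sh[2])
  binoc_o <- if (n_o > 0) {
    base <- nondom_o * stats::runif(n_o, 0.4, 0.85)
    draw_conditioned(base, cv, function(v) v < 0.95 * nondom_o)
  } else numeric(0)

  rate_dom <- c(dom_g, dom_t, dom_b, dom_o)
  rate_nondom <- c(nondom_g, nondom_t, nondom_b, nondom_o)
  rate_binoc <- c(binoc_g, binoc_t, binoc_b, binoc_o)
  n_all <- length(rate_dom)

  variance_of <- function(rate) {
    v <- switch(config$variance_model,
                poisson_like = rate,
                constant_cv = (max(cv, 0.05) * rate)^2)
    pmax(v, 1e-2)  # keep variances strictly positive for silent eyes
  }

  tibble::tibble(
    id = sprintf("n%03d", seq_len(n_all)),
    rate_dom = rate_dom,
    rate_nondom = rate_nondom,
    rate_binoc = rate_binoc,
    var_dom = variance_of(rate_dom),
    var_nondom = variance_of(rate_nondom),
    responsive_nondom = rep(c(FALSE, TRUE, TRUE, TRUE),
                            c(config$n_gate, config$n_true, n_b, n_o)),
    truth_label = rep(c("gate_facilitatory", "true_facilitatory",
                        "suppressive_between", "suppressive_other"),
                      c(config$n_gate, config$n_true, n_b, n_o))
  )
}

# Log-parabola mean contrast-sensitivity curve.
csf_curve <- function(sf, peak_sens, peak_sf, bw) {
  10^(log10(peak_sens) - ((log10(sf) - log10(peak_sf)) / bw)^2)
}

#' Generate a synthetic multi-study contrast-sensitivity dataset
#'
#' One row per subject per spatial frequency. Each study has a smooth
#' log-parabola mean sensitivity curve (peaking near 3 c/deg and falling
#' toward the highest frequency) at its own overall level, so that the
#' pooled studies span the wide sensitivity range a power-law fit requires.
#' Subjects get a lognormal level jitter shared across frequencies and eyes;
#' the right/left ratio is lognormal per row, so the better eye can switch
#' across frequencies. For enhancing subjects, binocular sensitivity follows
#' the configured rule applied to the better eye (gated power law, default)
#' or to both eyes (Minkowski), times lognormal noise; each enhancing
#' subject's noise vector is redrawn until a strict majority of their
#' frequencies show enhancement, mirroring how screened subjects enter real
#' analyses. Non-enhancing subjects get binocular sensitivity drawn just
#' below the better eye at every frequency.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with columns `study`, `subject`, `sf`, `sens_left`,
#'   `sens_right`, `sens_binoc`, `truth_enhancer`.
#' @export
generate_csf_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  # independent stream from the neural generator, derived from the one seed
  set.seed((config$seed * 7919L + 104729L) %% 2147483647L)
  cv <- config$noise_cv
  out <- vector("list", nrow(config$studies))

  for (i in seq_len(nrow(config$studies))) {
    st <- config$studies[i, ]
    sf <- st$sf[[1]]
    n_sf <- length(sf)
    mean_curve <- csf_curve(sf, st$peak_sens, config$csf_peak_sf, config$csf_bw)
    m_vec <- rep_len(config$csf_m, n_sf)
    nonenh <- if (i == config$nonenhancer_study) config$n_nonenhancers else 0L

    rows <- vector("list", st$n_subjects)
    for (s in seq_len(st$n_subjects)) {
      level <- exp(stats::rnorm(1, 0, config$subject_sd))
      delta <- stats::rnorm(n_sf, 0, config$interocular_ratio_sd)
      left <- mean_curve * level * exp(-delta / 2)
      right <- mean_curve * level * exp(delta / 2)
      best <- pmax(left, right)
      worst <- pmin(left, right)
      if (s <= nonenh) {
        binoc <- best * stats::runif(n_sf, 0.8, 0.98)
        enhancer <- FALSE
      } else {
        base <- switch(config$generator_csf,
          power_law = power_law_amplify(best, config$csf_params["a"],
                                        config$csf_params["n"]),
          minkowski = minkowski_combine(best, worst, m_vec)
        )
        binoc <- base * lognoise(n_sf, cv)
        if (cv > 0) {
          it <- 0
          while (sum(binoc > best) <= n_sf / 2 && it < 2000) {
            binoc <- base * lognoise(n_sf, cv)
            it <- it + 1
          }
        }
        enhancer <- TRUE
      }
      rows[[s]] <- tibble::tibble(
        study = st$study, subject = sprintf("%s_s%02d", st$study, s),
        sf = sf, sens_left = left, sens_right = right, sens_binoc = binoc,
        truth_enhancer = enhancer
      )
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
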