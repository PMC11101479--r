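#' Is the non-dominant eye's response reliable?
#'
#' Spike-reliability rule used when a dataset does not record whether the
#' non-dominant eye drives the neuron: the eye is considered non-responsive
#' when its rate is both below `frac` of the dominant rate and below an
#' absolute `floor` (spikes/s). Both thresholds are configurable.
#'
#' @param rate_dom,rate_nondom Mean firing rates (spikes/s).
#' @param frac Relative threshold (default 0.10).
#' @param floor Absolute threshold in spikes/s (default 5).
#' @return Logical vector: `TRUE` where the non-dominant eye is responsive.
#' @export
nondom_responsive <- function(rate_dom, rate_nondom, frac = 0.10, floor = 5) {
  check_nonnegative(rate_dom, "rate_dom")
  check_nonnegative(rate_nondom, "rate_nondom")
  !(rate_nondom < frac * rate_dom & rate_nondom < floor)
}

neuron_class_levels <- c("gate_facilitatory", "true_facilitatory",
                         "suppressive_between", "suppressive_other",
                         "non_interacting")

#' Classify binocular neurons into facilitatory/suppressive subtypes
#'
#' Assigns each neuron exactly one of five labels from its dominant-eye,
#' non-dominant-eye and binocular mean firing rates:
#'
#' * `gate_facilitatory` -- driven by one eye only (`responsive_nondom` is
#'   `FALSE`) but with binocular rate above the dominant rate: a binocular
#'   gate neuron.
#' * `true_facilitatory` -- driven by both eyes, binocular rate above the
#'   dominant rate.
#' * `suppressive_between` -- driven by both eyes with binocular rate lying
#'   between the non-dominant and dominant rates (inclusive): candidates for
#'   weighted-average combination ("Between" neurons).
#' * `suppressive_other` -- binocular rate below even the non-dominant rate.
#' * `non_interacting` -- anything else (e.g. a monocularly driven neuron
#'   whose rate barely changes under binocular stimulation).
#'
#' Boundaries are applied with relative tolerance `tol`: facilitation
#' requires `rate_binoc > rate_dom * (1 + tol)`, strong suppression requires
#' `rate_binoc < rate_nondom * (1 - tol)`, and exact ties with the dominant
#' rate fall in the between class (the between interval is closed).
#'
#' @param records Data frame with columns `rate_dom`, `rate_nondom`,
#'   `rate_binoc` and logical `responsive_nondom` (computed with
#'   [nondom_responsive()] if absent).
#' @param tol Relative tolerance for the facilitation/suppression boundaries
#'   (default 0.05).
#' @return `records` with a `class` column added (factor with the five
#'   levels above).
#' @export
classify_neurons <- function(records, tol = 0.05) {
  need <- c("rate_dom", "rate_nondom", "rate_binoc")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("classify_neurons(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_nonnegative(records$rate_dom, "rate_dom")
  check_nonnegative(records$rate_nondom, "rate_nondom")
  check_nonnegative(records$rate_binoc, "rate_binoc")
  if (!("responsive_nondom" %in% names(records))) {
    records$responsive_nondom <-
      nondom_responsive(records$rate_dom, records$rate_nondom)
  }
  cls <- classify_rule(records$rate_dom, records$rate_nondom,
                       records$rate_binoc, records$responsive_nondom, tol)
  records$class <- factor(cls, levels = neuron_class_levels)
  records
}

#' Classify a single neuron
#'
#' Scalar convenience wrapper around the rule table of [classify_neurons()].
#'
#' @inheritParams classify_neurons
#' @param rate_dom,rate_nondom,rate_binoc Mean firing rates (spikes/s).
#' @param responsive_nondom Does the non-dominant eye reliably drive spiking?
#' @return A single class label (character).
#' @export
classify_neuron <- function(rate_dom, rate_nondom, rate_binoc,
                            responsive_nondom = NULL, tol = 0.05) {
  if (is.null(responsive_nondom)) {
    responsive_nondom <- nondom_responsive(rate_dom, rate_nondom)
  }
  check_nonnegative(rate_dom, "rate_dom")
  check_nonnegative(rate_nondom, "rate_nondom")
  check_nonnegative(rate_binoc, "rate_binoc")
  classify_rule(rate_dom, rate_nondom, rate_binoc, responsive_nondom, tol)
}

classify_rule <- function(dom, nondom, binoc, responsive, tol) {
  n <- length(dom)
  out <- rep("non_interacting", n)
  facil <- binoc > dom * (1 + tol)
  out[facil & !responsive] <- "gate_facilitatory"
  out[facil & responsive] <- "true_facilitatory"
  between <- !facil & responsive & binoc >= nondom * (1 - tol)
  out[between] <- "suppressive_between"
  other <- !facil & !between & binoc < nondom * (1 - tol)
  out[other] <- "suppressive_other"
  out
}

#' Select the "Between" (mildly suppressive) neurons
#'
#' MacLeod's criterion: a suppressive binocular neuron is a candidate
#' weighted averager only when it is reliably driven by both eyes and its
#' binocular firing rate lies between the non-dominant and dominant
#' monocular rates. Returns exactly that subset, in input order.
#'
#' @param records Neuron table; classified with [classify_neurons()] first
#'   if a `class` column is absent.
#' @param tol Passed to [classify_neurons()] when classification is needed.
#' @return The `suppressive_between` rows of `records`.
#' @export
macleod_between_filter <- function(records, tol = 0.05) {
  if (!("class" %in% names(records))) {
    if (nrow(records) == 0) return(records)
    records <- classify_neurons(records, tol = tol)
  }
  records[records$class == "suppressive_between", , drop = FALSE]
}

#' Flag binocular enhancement for each (subject, spatial-frequency) row
#'
#' A row shows enhancement when binocular sensitivity strictly exceeds the
#' better monocular sensitivity.
#'
#' @param records CSF table with columns `sens_left`, `sens_right`,
#'   `sens_binoc`.
#' @return `records` with a logical `enhancing` column added.
#' @export
enhancement_flags <- function(records) {
  need <- c("sens_left", "sens_right", "sens_binoc")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("enhancement_flags(): missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  records$enhancing <-
    records$sens_binoc > pmax(records$sens_left, records$sens_right)
  records
}

#' Screen subjects by binocular enhancement
#'
#' A subject is retained for facilitatory modeling only when they show
#' binocular enhancement (binocular sensitivity above the better eye) at a
#' strict majority of the spatial frequencies tested. This mirrors the
#' exclusion of subjects who show no enhancement at most frequencies, often
#' associated with amblyopia or other binocular deficits.
#'
#' @param records CSF table with columns `study`, `subject`, `sens_left`,
#'   `sens_right`, `sens_binoc` (one row per subject x spatial frequency).
#' @return A tibble with one row per (study, subject): `n_sf`,
#'   `n_enhancing`, `include`.
#' @export
subject_enhancement_screen <- function(records) {
  records <- enhancement_flags(records)
  if (!("study" %in% names(records))) records$study <- "study"
  if (!("subject" %in% names(records))) {
    stop("subject_enhancement_screen(): missing `subject` column",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(records), .data$study, .data$subject),
    n_sf = dplyr::n(),
    n_enhancing = sum(.data$enhancing),
    .groups = "drop"
  )
  out$include <- out$n_enhancing > out$n_sf / 2
  out
}

#' Split monocular sensitivities into better and worse eye
#'
#' The better/worse assignment is made row by row (per subject per spatial
#' frequency), so the identity of the better eye may switch across
#' frequencies for the same subject. Averaging better-eye rather than
#' left-eye sensitivities is what the binocular system actually confronts:
#' left/right averaging across subjects hides interocular differences.
#'
#' @param records CSF table with columns `sens_left`, `sens_right`.
#' @return `records` with `sens_best` and `sens_worst` columns added.
#' @export
best_worst_split <- function(records) {
  need <- c("sens_left", "sens_right")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("best_worst_split(): missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  check_positive(records$sens_left, "sens_left")
  check_positive(records$sens_right, "sens_right")
  records$sens_best <- pmax(records$sens_left, records$sens_right)
  records$sens_worst <- pmin(records$sens_left, records$sens_right)
  records
}
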