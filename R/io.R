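neural_cols <- c("id", "rate_dom", "rate_nondom", "rate_binoc",
                 "var_dom", "var_nondom", "responsive_nondom")
csf_cols <- c("study", "subject", "sf", "sens_left", "sens_right",
              "sens_binoc")
default_sf_grid <- c(1, 1.5, 3, 6, 12, 18.5)

#' Read / write the neural firing-rate CSV schema
#'
#' One row per neuron: `id`, `rate_dom`, `rate_nondom`, `rate_binoc`
#' (spikes/s), `var_dom`, `var_nondom` (firing-rate variances),
#' `responsive_nondom` (logical), optionally `truth_label` and `class`.
#' Reading validates the header and every row; malformed or negative values
#' raise an error naming the offending row. `write_neural_csv()` followed by
#' `read_neural_csv()` is an identity.
#'
#' @param path File path.
#' @return `read_neural_csv()` returns a tibble of neuron records;
#'   `write_neural_csv()` returns `path` invisibly.
#' @export
read_neural_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(neural_cols, names(df))
  if (length(miss) > 0) {
    stop("read_neural_csv(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$responsive_nondom <- as.logical(df$responsive_nondom)
  num <- c("rate_dom", "rate_nondom", "rate_binoc", "var_dom", "var_nondom")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("read_neural_csv(): malformed value in column `%s`, row %d",
                   col, bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- which(df$rate_dom < 0 | df$rate_nondom < 0 | df$rate_binoc < 0)
  if (length(bad) > 0) {
    stop(sprintf("read_neural_csv(): negative firing rate in row %d", bad[1]),
         call. = FALSE)
  }
  bad <- which(is.na(df$responsive_nondom))
  if (length(bad) > 0) {
    stop(sprintf("read_neural_csv(): malformed `responsive_nondom` in row %d",
                 bad[1]), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_neural_csv
#' @param records Neuron table to write.
#' @export
write_neural_csv <- function(records, path) {
  miss <- setdiff(neural_cols, names(records))
  if (length(miss) > 0) {
    stop("write_neural_csv(): missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the contrast-sensitivity CSV schema
#'
#' One row per subject per spatial frequency: `study`, `subject`, `sf`
#' (c/deg), `sens_left`, `sens_right`, `sens_binoc` (linear contrast
#' sensitivity), optionally `truth_enhancer`. Duplicate
#' (study, subject, sf) keys are an error. Spatial frequencies outside the
#' conventional 1-18.5 c/deg grid are accepted with a notice, since grids
#' differ between studies.
#'
#' @param path File path.
#' @return `read_csf_csv()` returns a tibble of CSF records;
#'   `write_csf_csv()` returns `path` invisibly.
#' @export
read_csf_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(csf_cols, names(df))
  if (length(miss) > 0) {
    stop("read_csf_csv(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("sf", "sens_left", "sens_right", "sens_binoc")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop(sprintf("read_csf_csv(): malformed value in column `%s`, row %d",
                   col, bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- which(df$sens_left <= 0 | df$sens_right <= 0 | df$sens_binoc <= 0)
  if (length(bad) > 0) {
    stop(sprintf("read_csf_csv(): non-positive sensitivity in row %d", bad[1]),
         call. = FALSE)
  }
  key <- paste(df$study, df$subject, df$sf, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop(sprintf("read_csf_csv(): duplicate (study, subject, sf) key in row %d",
                 anyDuplicated(key)), call. = FALSE)
  }
  off_grid <- setdiff(unique(df$sf), default_sf_grid)
  if (length(off_grid) > 0) {
    message("read_csf_csv(): spatial frequencies outside the default grid: ",
            paste(off_grid, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname read_csf_csv
#' @param records CSF table to write.
#' @export
write_csf_csv <- function(records, path) {
  miss <- setdiff(csf_cols, names(records))
  if (length(miss) > 0) {
    stop("write_csf_csv(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(records$study, records$subject, records$sf, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop("write_csf_csv(): duplicate (study, subject, sf) key", call. = FALSE)
  }
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-dimensional plotting table for three-variable combination data
#'
#' Binocular input/output data are intrinsically three-dimensional (two
#' monocular responses in, one binocular response out). This transform plots
#' every series against the *observed* combined response: the observed
#' series then lies exactly on the 45-degree line in any monotone coordinate
#' system, the monocular series show each channel's relative contribution,
#' and model predictions deviate visibly from the diagonal where they miss.
#'
#' @param observed Observed combined responses.
#' @param strong,weak Monocular responses.
#' @param model_pred Model-predicted combined responses (one per record).
#' @param model_label Tag for the model series (default "model").
#' @return A tibble with columns `x` (observed combined), `series`
#'   (`combined`, `mono_strong`, `mono_weak`, or the model label), `y`.
#' @export
make_triple_plot_table <- function(observed, strong, weak, model_pred,
                                   model_label = "model") {
  n <- length(observed)
  if (length(strong) != n || length(weak) != n || length(model_pred) != n) {
    stop("make_triple_plot_table(): all inputs must have the same length",
         call. = FALSE)
  }
  tibble::tibble(
    x = rep(observed, 4),
    series = rep(c("combined", "mono_strong", "mono_weak", model_label),
                 each = n),
    y = c(observed, strong, weak, model_pred)
  )
}

#' Plot a triple-plot table
#'
#' Renders [make_triple_plot_table()] output with log-log axes by default
#' (the 45-degree identity of the combined series is preserved under any
#' monotone axis transform).
#'
#' @param table Output of [make_triple_plot_table()].
#' @param log_axes Use log10 scales (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_triple <- function(table, log_axes = TRUE) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$series,
                                           shape = .data$series)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::labs(x = "observed combined response",
                  y = "response magnitude") +
    ggplot2::theme_minimal()
  if (log_axes) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}
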