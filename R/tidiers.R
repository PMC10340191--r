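# broom-style tidiers for fitted objects and reports.

#' Tidy a training fit
#'
#' @param x An `hrcc_fit`.
#' @param ... Unused.
#' @return A long tibble with one row per epoch and metric
#'   (`epoch`, `metric`, `value`).
#' @export
tidy.hrcc_fit <- function(x, ...) {
  tidyr::pivot_longer(x$log, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' @rdname tidy.hrcc_fit
#' @return `glance()` returns a one-row tibble with the final and best
#'   state of the run.
#' @export
glance.hrcc_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    train_loss = last$train_loss,
    val_loss = last$val_loss,
    val_mean_auc = last$val_mean_auc,
    loss = x$loss,
    parameters = count_parameters(x$network)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `hrcc_metrics_report`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @export
tidy.hrcc_metrics_report <- function(x, ...) x$per_class

#' @rdname tidy.hrcc_metrics_report
#' @export
glance.hrcc_metrics_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mean_auc = x$mean_auc,
                                  threshold = x$threshold), x$macro)
}

#' Tidy a profile report
#'
#' @param x An `hrcc_profile_report`.
#' @param ... Unused.
#' @return The per-layer breakdown tibble.
#' @export
tidy.hrcc_profile_report <- function(x, ...) x$breakdown

#' @rdname tidy.hrcc_profile_report
#' @export
glance.hrcc_profile_report <- function(x, ...) {
  tibble::tibble(total_params = x$total_params,
                 total_flops = x$total_flops,
                 input_size = x$input_size,
                 flop_unit = x$flop_unit)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
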