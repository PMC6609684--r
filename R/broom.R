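#' Broom-style tidiers
#'
#' `tidy()` returns the per-element detail of a fitted object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x a fitted object from this package.
#' @param ... unused.
#' @return a tibble.
#' @name gc-tidiers
NULL

#' @rdname gc-tidiers
#' @export
tidy.gc_roc <- function(x, ...) x$curve

#' @rdname gc-tidiers
#' @export
glance.gc_roc <- function(x, ...) {
  tibble(auc = x$auc, n_positive = x$n_positive, n_negative = x$n_negative,
         positive = x$positive, direction = x$direction)
}

#' @rdname gc-tidiers
#' @export
tidy.gc_performance <- function(x, ...) x$per_class

#' @rdname gc-tidiers
#' @export
glance.gc_performance <- function(x, ...) {
  tibble(
    n = x$n, accuracy = x$accuracy, nir = x$nir$nir,
    nir_p_value = x$nir$p_value, kappa = x$kappa
  )
}

#' @rdname gc-tidiers
#' @export
tidy.gc_survfit <- function(x, ...) {
  fit <- x$fit
  strata <- if (is.null(fit$strata)) {
    rep(levels(x$data$.group)[1L], length(fit$time))
  } else {
    sub("^.group=", "", rep(names(fit$strata), fit$strata))
  }
  tibble(
    group = strata,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    estimate = fit$surv
  )
}

#' @rdname gc-tidiers
#' @export
glance.gc_survfit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n = nrow(x$data), n_events = sum(x$data$os_event)),
    x$logrank
  )
}

#' @rdname gc-tidiers
#' @export
tidy.gc_panel <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname gc-tidiers
#' @export
glance.gc_panel <- function(x, ...) {
  tibble(n_genes = length(x$genes), n = x$n)
}

#' @rdname gc-tidiers
#' @export
tidy.gc_tp53_calibration <- function(x, ...) x$roc$curve

#' @rdname gc-tidiers
#' @export
glance.gc_tp53_calibration <- function(x, ...) {
  tibble(cutoff = x$cutoff, youden_j = x$j, auc = x$auc, n = x$n)
}
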