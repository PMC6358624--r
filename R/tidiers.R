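#' Tidy a clustering fit
#'
#' @param x An `fs_fit` from [fs_mcmc()].
#' @param ... Unused.
#' @return Tibble (`id`, `cluster`, `certainty`).
#' @exportS3Method generics::tidy
tidy.fs_fit <- function(x, ...) {
  out <- x$partition
  if (nrow(x$trace$samples) >= 2) {
    cert <- assignment_certainty(x)
    out$certainty <- cert[cbind(seq_len(nrow(out)), out$cluster)]
  }
  out
}

#' @rdname tidy.fs_fit
#' @exportS3Method generics::glance
glance.fs_fit <- function(x, ...) {
  tibble::tibble(n = length(x$ids), K = x$K,
                 map_logpost = x$map_logpost,
                 c_factor = x$c_factor,
                 n_samples = nrow(x$trace$samples),
                 sm_accept = x$trace$sm_accepted / max(1, x$trace$sm_tried))
}

#' Tidy an exponential curve fit
#'
#' @param x An `exp_fit` from [fit_curve_exponential()].
#' @param ... Unused.
#' @return One row per component: `component`, `amplitude`, `rate_per_cm`,
#'   `g`, `intercept`, `rss`.
#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$lambda),
                 amplitude = x$A, rate_per_cm = x$lambda, g = x$g,
                 intercept = x$c, rss = x$rss)
}

#' @rdname tidy.exp_fit
#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, rss = x$rss,
                 n_bins = nrow(x$data), converged = x$converged)
}

#' Tidy an ancestry profile
#'
#' @param x An `ancestry_profile` from [fit_ancestry_profile()].
#' @param ... Unused.
#' @return Tibble (`group`, `coefficient`).
#' @exportS3Method generics::tidy
tidy.ancestry_profile <- function(x, ...) {
  tibble::tibble(group = x$group, coefficient = x$coefficient)
}

#' @rdname tidy.ancestry_profile
#' @exportS3Method generics::glance
glance.ancestry_profile <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x), n_nonzero = sum(x$coefficient > 0),
                 residual = attr(x, "residual"),
                 nonunique = attr(x, "nonunique"))
}

#' Tidy an admixture event
#'
#' @param x An `admixture_event` from [infer_two_way_event()].
#' @param ... Unused.
#' @return One row per donor group with minor/major source weights.
#' @exportS3Method generics::tidy
tidy.admixture_event <- function(x, ...) {
  if (is.null(x$minor_profile))
    return(tibble::tibble(group = character(), minor = numeric(),
                          major = numeric()))
  tibble::tibble(group = names(x$minor_profile),
                 minor = as.numeric(x$minor_profile),
                 major = as.numeric(x$major_profile))
}

#' @rdname tidy.admixture_event
#' @exportS3Method generics::glance
glance.admixture_event <- function(x, ...) {
  tibble::tibble(detected = x$detected, p_evidence = x$p_evidence,
                 g = x$g, year = x$year, proportion = x$proportion)
}
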