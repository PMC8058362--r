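#' Mean target copies per droplet from partition counts
#'
#' In droplet digital PCR the sample is partitioned into droplets and each
#' droplet is scored positive or negative; under random partitioning the
#' number of template copies per droplet is Poisson, so the mean
#' concentration follows from the negative fraction:
#' `lambda = -ln(1 - n_positive / n_droplets)`.
#'
#' @param n_positive Number of positive droplets.
#' @param n_droplets Total droplets (must exceed `n_positive`; an
#'   all-positive well is saturated and carries no concentration
#'   information).
#' @return Mean copies per droplet.
#' @export
poisson_lambda <- function(n_positive, n_droplets) {
  stopifnot(n_positive >= 0, n_droplets > 0)
  if (any(n_positive >= n_droplets)) {
    abort("saturated well: every droplet positive, lambda is unbounded")
  }
  -log(1 - n_positive / n_droplets)
}

#' Copy number from a target/reference well pair
#'
#' Estimates absolute copy number as
#' `cn = reference_cn * lambda_target / lambda_reference`, with a 95%
#' interval from the delta method on the log scale (each positive fraction
#' is binomial; `var(log lambda) = p / (n (1-p) lambda^2)`). The carrier
#' call requires the whole interval to clear the boundary: `duplication`
#' when the lower limit exceeds 2.5, `deletion` when the upper limit is
#' below 1.5, `normal` when the interval lies within (1.5, 2.5), and
#' `ambiguous` otherwise. Values close to 3 indicate a single-copy
#' duplication.
#'
#' @param target,reference One-row well tibbles (columns `sample_id`,
#'   `n_droplets`, `n_positive`) for the target and reference assays of
#'   the same sample.
#' @param reference_cn Copies of the reference locus (2 for an autosomal
#'   reference such as RPP30).
#' @return A one-row tibble of class `cn_estimate`: `sample_id`, `cn`,
#'   `ci_low`, `ci_high`, `call`.
#' @export
copy_number <- function(target, reference, reference_cn = 2.0) {
  if (!identical(target$sample_id, reference$sample_id)) {
    abort("target and reference wells must come from the same sample")
  }
  lam_t <- poisson_lambda(target$n_positive, target$n_droplets)
  lam_r <- poisson_lambda(reference$n_positive, reference$n_droplets)
  if (lam_r == 0) {
    abort("reference well has no positive droplets; ratio undefined")
  }
  cn <- reference_cn * lam_t / lam_r
  var_log <- function(n_pos, n_tot, lam) {
    p <- n_pos / n_tot
    if (p == 0) return(0)
    p / (n_tot * (1 - p) * lam^2)
  }
  se_log <- sqrt(
    var_log(target$n_positive, target$n_droplets, lam_t) +
      var_log(reference$n_positive, reference$n_droplets, lam_r)
  )
  ci_low <- cn * exp(-qnorm(0.975) * se_log)
  ci_high <- cn * exp(qnorm(0.975) * se_log)
  call <- if (ci_low > 2.5) {
    "duplication"
  } else if (ci_high < 1.5) {
    "deletion"
  } else if (ci_low >= 1.5 && ci_high <= 2.5) {
    "normal"
  } else {
    "ambiguous"
  }
  out <- tibble::tibble(
    sample_id = target$sample_id, cn = cn,
    ci_low = ci_low, ci_high = ci_high, call = call
  )
  class(out) <- c("cn_estimate", class(out))
  out
}

#' Copy-number estimates for a table of wells
#'
#' Pairs each sample's target-assay well with its reference-assay well and
#' estimates copy number per sample and target assay.
#'
#' @param wells Well tibble with columns `sample_id`, `assay`,
#'   `n_droplets`, `n_positive`; one reference-assay row per sample.
#' @param reference_assay Assay name of the reference locus.
#' @param reference_cn Copies of the reference locus.
#' @return A tibble with one `cn_estimate` row per (sample, target assay).
#' @export
estimate_copy_numbers <- function(wells, reference_assay = "reference_rpp30",
                                  reference_cn = 2.0) {
  bad <- wells$n_positive < 0 | wells$n_positive > wells$n_droplets
  if (any(bad)) abort("n_positive must lie in [0, n_droplets]")
  refs <- wells[wells$assay == reference_assay, ]
  targets <- wells[wells$assay != reference_assay, ]
  if (nrow(targets) == 0L) {
    out <- tibble::tibble(
      sample_id = character(), locus = character(), cn = double(),
      ci_low = double(), ci_high = double(), call = character()
    )
    class(out) <- c("cn_estimate", class(out))
    return(out)
  }
  if (anyDuplicated(refs$sample_id) > 0L) {
    abort("more than one reference well per sample")
  }
  out <- purrr::pmap(
    list(seq_len(nrow(targets))),
    function(i) {
      tgt <- targets[i, ]
      ref <- refs[refs$sample_id == tgt$sample_id, ]
      if (nrow(ref) != 1L) {
        abort(paste0("no reference well for sample ", tgt$sample_id))
      }
      est <- copy_number(tgt, ref, reference_cn)
      est$locus <- tgt$assay
      est
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::relocate("sample_id", "locus")
  class(out) <- c("cn_estimate", class(out))
  out
}

#' @rdname copy_number
#' @param x A `cn_estimate` tibble.
#' @param ... Unused.
#' @method glance cn_estimate
#' @export
glance.cn_estimate <- function(x, ...) {
  tibble::tibble(
    n_samples = dplyr::n_distinct(x$sample_id),
    n_duplication = sum(x$call == "duplication"),
    n_deletion = sum(x$call == "deletion"),
    n_ambiguous = sum(x$call == "ambiguous")
  )
}
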