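#' Log R ratio from observed and expected probe intensities
#'
#' @param r_observed,r_expected Positive total probe intensities.
#' @return `log2(r_observed / r_expected)`; 0 for a typical two-copy
#'   probe, about +0.585 for the ideal three-copy ratio (3/2), attenuated
#'   in practice.
#' @export
compute_lrr <- function(r_observed, r_expected) {
  if (any(r_observed <= 0) || any(r_expected <= 0)) {
    abort("probe intensities must be positive")
  }
  log2(r_observed / r_expected)
}

#' Per-sample missing call rate
#'
#' The fraction of probes with no genotype call (`NC`) over all probes.
#'
#' @param probes Probe tibble for one sample (column `call`).
#' @return Fraction in \[0, 1\].
#' @export
missing_call_rate <- function(probes) {
  if (nrow(probes) == 0L) abort("sample has no probes")
  mean(probes$call == "NC")
}

#' Array sample quality control
#'
#' Samples whose missing call rate exceeds `max_missing` fail QC and must
#' be excluded from copy-number calling: an elevated no-call rate together
#' with distorted BAF/LRR tracks is the signature of sample contamination.
#' The boundary is inclusive: a rate of exactly `max_missing` passes.
#'
#' @param probes Probe tibble for one sample.
#' @param max_missing Highest acceptable missing call rate (default 0.01,
#'   i.e. call rate of at least 99%).
#' @return `"pass"` or `"fail"`.
#' @export
sample_qc <- function(probes, max_missing = 0.01) {
  if (missing_call_rate(probes) > max_missing) "fail" else "pass"
}

#' Configuration of the BAF/LRR segmentation model
#'
#' A three-state hidden Markov model over position-sorted probes with
#' states for one, two and three copies. LRR emissions are Gaussian around
#' the state mean (`-lrr_del`, 0, `+lrr_dup`); BAF emissions for
#' heterozygous-range probes are Gaussian mixtures over the state's
#' heterozygous clusters (0.5 for two copies; 1/3 and 2/3 for a
#' duplication; none for a deletion). Probes with BAF near 0 or 1
#' (homozygous) or without a genotype call are uninformative for BAF and
#' contribute through LRR only.
#'
#' @param min_probes Minimum probes for a reported segment.
#' @param lrr_dup Expected LRR elevation in a three-copy state. The
#'   default +0.4 is attenuated from the ideal `log2(3/2) = 0.585`,
#'   matching empirical array behaviour.
#' @param lrr_del Expected LRR depression (magnitude) in a one-copy state.
#' @param baf_sd,lrr_sd Emission standard deviations assumed by the model.
#' @param trans_prob Per-probe probability of switching copy-number state.
#' @param hom_cut BAF distance from 0/1 below which a probe is treated as
#'   homozygous.
#' @param outlier_frac Mixture weight given to a flat outlier component in
#'   each emission density.
#' @return A named list of class `cnv_config`.
#' @export
cnv_config <- function(min_probes = 10, lrr_dup = 0.4, lrr_del = 0.6,
                       baf_sd = 0.05, lrr_sd = 0.2, trans_prob = 1e-4,
                       hom_cut = 0.15, outlier_frac = 0.01) {
  stopifnot(min_probes >= 1, lrr_dup > 0, lrr_del > 0, trans_prob > 0,
    trans_prob < 0.5)
  structure(
    list(
      min_probes = min_probes, lrr_dup = lrr_dup, lrr_del = lrr_del,
      baf_sd = baf_sd, lrr_sd = lrr_sd, trans_prob = trans_prob,
      hom_cut = hom_cut, outlier_frac = outlier_frac
    ),
    class = "cnv_config"
  )
}

# log emission matrix (probes x states CN1/CN2/CN3)
cnv_emissions <- function(baf, call, lrr, cfg) {
  n <- length(baf)
  lrr_mu <- c(-cfg$lrr_del, 0, cfg$lrr_dup)
  out <- matrix(0, n, 3L)
  flat <- cfg$outlier_frac
  for (s in 1:3) {
    l_dens <- (1 - flat) * dnorm(lrr, lrr_mu[s], cfg$lrr_sd) + flat
    out[, s] <- log(l_dens)
  }
  het <- call != "NC" & baf > cfg$hom_cut & baf < 1 - cfg$hom_cut
  if (any(het)) {
    b <- baf[het]
    b_dens <- cbind(
      rep(0, length(b)), # CN1: no heterozygous cluster
      dnorm(b, 0.5, cfg$baf_sd), # CN2
      0.5 * dnorm(b, 1 / 3, cfg$baf_sd) + 0.5 * dnorm(b, 2 / 3, cfg$baf_sd)
    )
    out[het, ] <- out[het, , drop = FALSE] + log((1 - flat) * b_dens + flat)
  }
  out
}

viterbi3 <- function(log_emit, trans_prob) {
  n <- nrow(log_emit)
  log_trans <- matrix(log(trans_prob), 3L, 3L)
  diag(log_trans) <- log(1 - 2 * trans_prob)
  log_init <- log(c(trans_prob, 1 - 2 * trans_prob, trans_prob))
  delta <- matrix(-Inf, n, 3L)
  back <- matrix(0L, n, 3L)
  delta[1L, ] <- log_init + log_emit[1L, ]
  for (i in seq_len(n)[-1L]) {
    cand <- delta[i - 1L, ] + log_trans # rows: from, cols: to
    back[i, ] <- max.col(t(cand), ties.method = "first")
    delta[i, ] <- cand[cbind(back[i, ], 1:3)] + log_emit[i, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (i in rev(seq_len(n - 1L))) {
    path[i] <- back[i + 1L, path[i + 1L]]
  }
  path
}

#' Call copy-number segments from a BAF/LRR probe track
#'
#' Runs the three-state hidden Markov model of [cnv_config()] over each
#' chromosome independently (Viterbi decoding) and reports maximal runs of
#' non-diploid state with at least `min_probes` probes as segments.
#'
#' @param probes Probe tibble for one QC-passing sample: columns
#'   `probe_id`, `chrom`, `pos`, `call` (`AA`/`AB`/`BB`/`NC`), `baf`,
#'   `lrr`, sorted by position within chromosome.
#' @param config A [cnv_config()].
#' @return A tibble of class `cnv_segments` with columns `chrom`, `start`,
#'   `end` (1-based inclusive probe positions), `copy_number` (1 or 3),
#'   `n_probes`, `mean_lrr`, `het_baf_lower`, `het_baf_upper` (the two
#'   heterozygous BAF cluster means inside a duplication; `NA` for
#'   deletions).
#' @export
call_cnv_segments <- function(probes, config = cnv_config()) {
  stopifnot(all(c("chrom", "pos", "call", "baf", "lrr") %in% names(probes)))
  if (any(probes$baf < 0 | probes$baf > 1, na.rm = TRUE)) {
    abort("BAF values must lie in [0, 1]")
  }
  segs <- probes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(chr_probes, key) {
      if (is.unsorted(chr_probes$pos, strictly = FALSE)) {
        abort("probes must be sorted by position within chromosome")
      }
      path <- viterbi3(
        cnv_emissions(chr_probes$baf, chr_probes$call, chr_probes$lrr,
          config),
        config$trans_prob
      )
      runs <- rle(path)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- runs$values != 2L & runs$lengths >= config$min_probes
      purrr::pmap(
        list(starts[keep], ends[keep], runs$values[keep]),
        function(i0, i1, state) {
          inside <- chr_probes[i0:i1, ]
          het_lo <- inside$baf[inside$call != "NC" &
            inside$baf > config$hom_cut & inside$baf <= 0.5]
          het_hi <- inside$baf[inside$call != "NC" &
            inside$baf > 0.5 & inside$baf < 1 - config$hom_cut]
          tibble::tibble(
            chrom = key$chrom,
            start = inside$pos[1L],
            end = inside$pos[nrow(inside)],
            copy_number = c(1L, 2L, 3L)[state],
            n_probes = nrow(inside),
            mean_lrr = mean(inside$lrr),
            het_baf_lower = if (state == 3L) mean(het_lo) else NA_real_,
            het_baf_upper = if (state == 3L) mean(het_hi) else NA_real_
          )
        }
      ) |>
        dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  if (nrow(segs) == 0L) {
    segs <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      copy_number = integer(), n_probes = integer(), mean_lrr = double(),
      het_baf_lower = double(), het_baf_upper = double()
    )
  }
  segs <- dplyr::arrange(segs, .data$chrom, .data$start)
  class(segs) <- c("cnv_segments", class(segs))
  segs
}

#' Drop small copy-number segments
#'
#' Segments spanning fewer than `min_size_bp` base pairs (closed-interval
#' span `end - start + 1`) are removed; small array calls are dominated by
#' artefacts.
#'
#' @param segs A segment tibble from [call_cnv_segments()].
#' @param min_size_bp Minimum retained span (default 80,000 bp).
#' @return The filtered segment tibble.
#' @export
filter_segments <- function(segs, min_size_bp = 80000) {
  keep <- (segs$end - segs$start + 1) >= min_size_bp
  out <- segs[keep, ]
  class(out) <- class(segs)
  out
}

#' Genes overlapped by copy-number segments
#'
#' Closed-interval overlap of at least one base pair on the same
#' chromosome and genome build.
#'
#' @param segs Segment tibble.
#' @param genes Gene-interval tibble (see [read_gene_intervals()]).
#' @return `segs` with a list-column `genes` of overlapping gene names.
#' @export
annotate_segment_genes <- function(segs, genes) {
  segs$genes <- purrr::pmap(
    list(segs$chrom, segs$start, segs$end),
    function(chrom, start, end) {
      hit <- genes$chrom == chrom & genes$start <= end & genes$end >= start
      genes$gene[hit]
    }
  )
  segs
}

#' @rdname call_cnv_segments
#' @param x A `cnv_segments` tibble.
#' @param ... Unused.
#' @method glance cnv_segments
#' @export
glance.cnv_segments <- function(x, ...) {
  tibble::tibble(
    n_segments = nrow(x),
    n_duplications = sum(x$copy_number > 2),
    n_deletions = sum(x$copy_number < 2),
    total_bp = sum(x$end - x$start + 1)
  )
}
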