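# Bimodality testing and binarization of network abundance.

#' Hartigan dip statistic
#'
#' Maximum distance between the empirical CDF and the closest unimodal CDF,
#' computed exactly by greatest-convex-minorant / least-concave-majorant
#' iteration over the candidate modal interval.  Satisfies
#' `1/(2n) <= D <= 1/4`; a sample of identical values is degenerate (a point
#' mass is unimodal) and returns the lower bound with a warning.
#'
#' @param x numeric vector, `n >= 4`, finite.
#' @return list with `dip`, the modal interval `modal_lo`/`modal_hi`, and `n`.
#' @export
dip_statistic <- function(x) {
  r <- .dip_stat_cpp(as.numeric(x))
  if (r$degenerate) warning("all values identical: degenerate point mass")
  list(dip = r$dip, modal_lo = r$modal_lo, modal_hi = r$modal_hi,
       n = length(x))
}

#' Bootstrap dip test of unimodality
#'
#' The null distribution is the dip of `B` uniform(0,1) samples of size `n`
#' (Hartigan's standard choice, conservative among unimodal nulls); the
#' p-value uses the add-one rule `(r + 1) / (B + 1)` where `r` counts null
#' dips at least as large as the observed dip.  Reproducible under a fixed
#' seed.
#'
#' @param x numeric vector, `n >= 4`.
#' @param B bootstrap replicates (>= 100; the reference analysis used 10,000).
#' @param seed optional seed for the null draws (caller's RNG is restored).
#' @param alpha significance level recorded in the result.
#' @return list of class `dip_result`: `dip`, `p_value`, `n`, `B`,
#'   `modal_lo`, `modal_hi`, `significant`, `alpha`.
#' @export
dip_test <- function(x, B = 10000, seed = NULL, alpha = 0.05) {
  if (B < 100) stop("B must be >= 100")
  ds <- dip_statistic(x)
  nulls <- with_seed(seed, .dip_null_cpp(as.integer(length(x)), as.integer(B)))
  p <- (sum(nulls >= ds$dip) + 1) / (B + 1)
  structure(list(dip = ds$dip, p_value = p, n = ds$n, B = as.integer(B),
                 modal_lo = ds$modal_lo, modal_hi = ds$modal_hi,
                 significant = p < alpha, alpha = alpha),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.4f, p = %.4g (n = %d, B = %d)\n",
              x$dip, x$p_value, x$n, x$B))
  cat(sprintf("modal interval [%.4g, %.4g]; %ssignificant at alpha = %g\n",
              x$modal_lo, x$modal_hi, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Antimode binarization threshold
#'
#' The threshold is the minimum of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth) restricted to the open interval
#' between the two largest density modes -- the operational reading of
#' "where a minimum value for the dip was reached".  As a consistency check
#' the threshold is compared with the dip's modal interval: for a bimodal
#' sample that interval tracks one of the two clusters, so a threshold that
#' cuts *through* it (more than one bandwidth inside either end) would be
#' splitting a mode, and a warning is emitted.
#'
#' @param x the abundance vector (per mille).
#' @param dr the [dip_test()] result for `x`; must be significant --
#'   binarizing a unimodal distribution is refused.
#' @return list with `threshold`, the KDE `bandwidth`, and the dip modal
#'   interval for reference.
#' @export
antimode_threshold <- function(x, dr) {
  stopifnot(inherits(dr, "dip_result"))
  if (!isTRUE(dr$significant)) {
    stop("dip test not significant: no defensible binarization threshold")
  }
  den <- density(x, bw = "nrd0")
  peaks <- which(diff(sign(diff(den$y))) == -2) + 1L
  if (length(peaks) < 2) {
    # fall back to grid ends if smoothing merged the modes
    peaks <- c(1L, length(den$y))
  }
  top2 <- sort(peaks[order(den$y[peaks], decreasing = TRUE)][1:2])
  seg <- den$x >= den$x[top2[1]] & den$x <= den$x[top2[2]]
  thr <- den$x[seg][which.min(den$y[seg])]
  if (thr > dr$modal_lo + den$bw && thr < dr$modal_hi - den$bw) {
    warning(sprintf(
      "antimode %.3g cuts through the dip modal interval [%.3g, %.3g]",
      thr, dr$modal_lo, dr$modal_hi))
  }
  list(threshold = thr, bandwidth = den$bw,
       modal_lo = dr$modal_lo, modal_hi = dr$modal_hi)
}

#' Assign the four-way network state per sample
#'
#' A network is "present" when its abundance is at or above its threshold
#' (closed on the right, so a sample exactly at threshold counts as present).
#' nEQR, where available, is dichotomized at the deterioration cutoff.
#'
#' @param na a [network_abundance()] data.frame.
#' @param thr_S,thr_N binarization thresholds (per mille); pass the
#'   [antimode_threshold()] values or user overrides.  `NA` for a network
#'   whose dip test was not significant marks it absent everywhere (with a
#'   prominent warning).
#' @param meta optional [sample_metadata()] supplying `neqr`.
#' @param cfg a [run_config()] (supplies `neqr_cutoff`).
#' @return data.frame of class `state_table`: `sample_id`, `abund_S`,
#'   `abund_N`, `S_present`, `N_present`,
#'   `state` in {S_only, N_only, both, neither}, `neqr`, `deteriorated`.
#' @export
assign_states <- function(na, thr_S, thr_N, meta = NULL, cfg = run_config()) {
  drop <- !is.finite(na$abund_S) | !is.finite(na$abund_N)
  if (any(drop)) {
    message("assign_states: excluding ", sum(drop),
            " sample(s) with missing abundance")
    na <- na[!drop, ]
  }
  S_present <- if (is.na(thr_S)) {
    warning("S network dip not significant: S marked absent in all samples")
    rep(FALSE, nrow(na))
  } else na$abund_S >= thr_S
  N_present <- if (is.na(thr_N)) {
    warning("N network dip not significant: N marked absent in all samples")
    rep(FALSE, nrow(na))
  } else na$abund_N >= thr_N
  state <- ifelse(S_present & N_present, "both",
                  ifelse(S_present, "S_only",
                         ifelse(N_present, "N_only", "neither")))
  neqr <- rep(NA_real_, nrow(na))
  if (!is.null(meta)) {
    neqr <- meta$neqr[match(na$sample_id, meta$sample_id)]
  }
  st <- data.frame(na, S_present = S_present, N_present = N_present,
                   state = state, neqr = neqr,
                   deteriorated = neqr < cfg$neqr_cutoff,
                   stringsAsFactors = FALSE)
  class(st) <- c("state_table", "data.frame")
  counts <- table(factor(state, c("S_only", "N_only", "both", "neither")))
  message("assign_states: ", paste(names(counts), counts, sep = "=",
                                   collapse = ", "))
  st
}
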