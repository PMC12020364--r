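# Odds ratios, categorical and rank tests, FDR, ecological profiles.

#' Odds ratio with Altman 95% confidence interval
#'
#' `OR = (a/b) / (c/d)` with log-scale interval
#' `ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)`.  If any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells first and the
#' `corrected` flag is set.
#'
#' @param a,b,c,d the 2x2 cells: exposed-outcome, exposed-no-outcome,
#'   unexposed-outcome, unexposed-no-outcome.  `a` may also be a length-4
#'   vector or 2x2 matrix in that order.
#' @return list of class `odds_ratio_result`: `or`, `ci` (length 2),
#'   `corrected`, `cells`.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  cells <- if (is.null(b)) as.numeric(a) else c(a, b, c, d)
  stopifnot(length(cells) == 4)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  if (sum(cells) == 0) stop("empty contingency table")
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[1] / cc[2]) / (cc[3] / cc[4])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  structure(list(or = or, ci = ci, corrected = corrected, cells = cells),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR = %.3g (95%% CI %.3g-%.3g)%s\n", x$or, x$ci[1], x$ci[2],
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Deterioration risk of a network state
#'
#' Builds the 2x2 table of network presence against dichotomized nEQR
#' (deteriorated = nEQR below the run cutoff) and delegates to
#' [odds_ratio()].  Samples with missing nEQR are excluded and counted.
#' Samples in state "both"/"neither" are included: exposure is the presence
#' flag, not the exclusive state.
#'
#' @param st a [assign_states()] state table.
#' @param exposure `"S_present"` or `"N_present"`.
#' @return an `odds_ratio_result` with extra fields `exposure`, `n_used`,
#'   `n_missing`.
#' @export
deterioration_risk <- function(st, exposure = c("S_present", "N_present")) {
  exposure <- match.arg(exposure)
  ok <- !is.na(st$deteriorated)
  n_missing <- sum(!ok)
  if (n_missing) {
    message("deterioration_risk: ", n_missing, " sample(s) without nEQR excluded")
  }
  e <- st[[exposure]][ok]
  y <- st$deteriorated[ok]
  if (!any(e) || all(e)) stop("zero margin: exposure '", exposure,
                              "' is constant after exclusions")
  if (!any(y) || all(y)) stop("zero margin: deterioration outcome is constant")
  res <- odds_ratio(sum(e & y), sum(e & !y), sum(!e & y), sum(!e & !y))
  res$exposure <- exposure
  res$n_used <- sum(ok)
  res$n_missing <- n_missing
  res
}

#' Pearson chi-square test of independence
#'
#' No continuity correction (matching the MATLAB `crosstab` convention the
#' reference analysis used); a warning is issued when any expected count is
#' below 5.
#'
#' @param labels_a,labels_b categorical vectors of equal length.
#' @return list with `chi2`, `df`, `p`.
#' @export
crosstab_chi2 <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("both variables need at least 2 levels")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("expected counts below 5; asymptotic p-value may be inaccurate")
  }
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Kruskal-Wallis rank test
#'
#' @param values numeric vector.
#' @param groups categorical vector of the same length, >= 2 non-empty groups.
#' @return list with `H` (tie-corrected), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  res <- kruskal.test(values, groups)
  list(H = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric vector of p-values in \[0,1\] (`NA` passed through).
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' AMBI tolerance-group correlation profile
#'
#' Spearman correlation between per-sample network abundance and the summed
#' macrofauna abundance of each AMBI tolerance group (0 = very sensitive to
#' organic enrichment .. 6 = first-order opportunist), with BH adjustment
#' across groups.  Groups with constant abundance are flagged undefined.
#'
#' @param na a [network_abundance()] data.frame.
#' @param mf a [macrofauna_table()].
#' @param network `"S"` or `"N"`.
#' @return data.frame: tolerance_group, rho, p, q, n.
#' @export
tolerance_profile <- function(na, mf, network = c("S", "N")) {
  network <- match.arg(network)
  common <- intersect(na$sample_id, rownames(mf$abundance))
  if (length(common) < 10) stop("fewer than 10 overlapping samples")
  x <- na[[paste0("abund_", network)]][match(common, na$sample_id)]
  ab <- mf$abundance[common, , drop = FALSE]
  groups <- sort(unique(mf$tolerance[!is.na(mf$tolerance)]))
  rows <- lapply(groups, function(g) {
    taxa <- names(mf$tolerance)[!is.na(mf$tolerance) & mf$tolerance == g]
    taxa <- intersect(taxa, colnames(ab))
    if (!length(taxa)) return(NULL)
    tot <- rowSums(ab[, taxa, drop = FALSE])
    s <- spearman_rho(x, tot)
    data.frame(tolerance_group = g, rho = s$rho, p = s$p, n = length(common))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Correlation of network abundance with continuous covariates
#'
#' Spearman rho of per-sample network abundance against each requested
#' metadata field, BH-adjusted across the requested family.  Fields with
#' fewer than 10 non-missing values or zero variance are flagged undefined.
#'
#' @param na a [network_abundance()] data.frame.
#' @param meta a [sample_metadata()].
#' @param fields character vector of metadata column names.
#' @param network `"S"` or `"N"`.
#' @return data.frame: field, rho, p, q, n.
#' @export
covariate_association <- function(na, meta,
                                  fields = c("distance", "toc", "ph", "redox",
                                             "pelite", "cu", "zn", "total_n"),
                                  network = c("S", "N")) {
  network <- match.arg(network)
  x_all <- na[[paste0("abund_", network)]]
  idx <- match(na$sample_id, meta$sample_id)
  rows <- lapply(fields, function(f) {
    if (!f %in% names(meta)) return(NULL)
    v <- meta[[f]][idx]
    ok <- !is.na(v) & is.finite(x_all)
    if (sum(ok) < 10 || var(v[ok]) == 0) {
      return(data.frame(field = f, rho = NA_real_, p = NA_real_, n = sum(ok)))
    }
    s <- spearman_rho(x_all[ok], v[ok])
    data.frame(field = f, rho = s$rho, p = s$p, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}
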