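# Genus-level Spearman co-occurrence network, hub detection and membership.

#' Spearman rank correlation with large-sample p-value
#'
#' Pearson correlation of midranks; the p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of freedom, adequate at
#' the cohort sizes this pipeline targets.  If either vector has zero rank
#' variance the correlation is undefined and `rho`/`p` are `NA` (callers log
#' and exclude such pairs).
#'
#' @param x,y numeric vectors of equal length >= 4; ties allowed.
#' @return list with `rho` and `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("spearman_rho requires n >= 4")
  rx <- rank(x)
  ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(rx, ry)
  list(rho = rho, p = spearman_p(rho, n))
}

spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  one <- abs(rho) >= 1 - 1e-15
  p[one & !is.na(rho)] <- 0
  i <- !one & !is.na(rho)
  tt <- rho[i] * sqrt((n - 2) / (1 - rho[i]^2))
  p[i] <- 2 * pt(-abs(tt), df = n - 2)
  p[is.na(rho)] <- NA_real_
  p
}

#' Build the all-pairs genus correlation network
#'
#' Computes Spearman rho, the t-approximation p-value and Benjamini-Hochberg
#' q-value for every genus pair of a per-mille profile, plus per-genus counts
#' of strong positive (`rho > rho_pos`) and strong negative (`rho < rho_neg`)
#' edges.  Genera failing the prevalence filter (detected in fewer than
#' `prevalence_min` of samples or mean abundance below `abundance_min` per
#' mille), unclassified buckets and zero-variance columns are excluded and
#' logged; set the filter to zero in the [run_config()] for full-cohort mode.
#'
#' @param gp a `genus_profile` from [to_relative_permille()].
#' @param cfg a [run_config()].
#' @return list of class `cooccurrence_network`: `genera`, `phylum`, matrices
#'   `rho`, `p`, `q`, degree counts `n_pos`, `n_neg`, thresholds and sample
#'   size.
#' @export
build_network <- function(gp, cfg = run_config()) {
  if (nrow(gp) < 4) stop("network inference requires >= 4 samples")
  keep <- rep(TRUE, ncol(gp))
  bucket <- attr(gp, "bucket")
  if (!is.null(bucket)) keep <- keep & !bucket
  prev <- colMeans(gp > 0)
  keep <- keep & prev >= cfg$prevalence_min & colMeans(gp) >= cfg$abundance_min
  keep <- keep & apply(gp, 2, var) > 0
  dropped <- ncol(gp) - sum(keep)
  if (sum(keep) < 2) stop("fewer than 2 genera remain after filtering")
  message(sprintf("build_network: %d genera retained, %d filtered out",
                  sum(keep), dropped))
  m <- gp[, keep, drop = FALSE]
  if (isTRUE(cfg$use_clr)) {
    lm_ <- log(m + 0.5)
    m <- lm_ - rowMeans(lm_)
  }
  n <- nrow(m)
  rho <- cor(m, method = "spearman")
  p <- matrix(spearman_p(rho, n), ncol(m), dimnames = dimnames(rho))
  diag(p) <- NA_real_
  ut <- upper.tri(rho)
  q <- matrix(NA_real_, ncol(m), ncol(m), dimnames = dimnames(rho))
  q[ut] <- p.adjust(p[ut], method = cfg$fdr_method)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  n_pos <- rowSums(rho > cfg$rho_pos) - 1 # diagonal rho = 1 removed
  n_neg <- rowSums(rho < cfg$rho_neg)
  ph <- attr(gp, "genus_phylum")
  structure(list(genera = colnames(m),
                 phylum = if (!is.null(ph)) ph[colnames(m)] else NULL,
                 rho = rho, p = p, q = q, n_pos = n_pos, n_neg = n_neg,
                 rho_pos = cfg$rho_pos, rho_neg = cfg$rho_neg,
                 n_samples = n, n_filtered = dropped),
            class = "cooccurrence_network")
}

#' Identify the opposing hub pair
#'
#' The first hub is the genus with the most strong negative edges; the second
#' is the genus most negatively correlated with the first.  The hub with the
#' larger negative degree is labelled S-like (the sulfur-oxidizer role in the
#' motivating cohort), the other N-like; callers may override roles from
#' taxonomy.  Errors if the network contains no edge below `rho_neg`: absence
#' of opposing structure is reported, never silently bridged.
#'
#' @param net a [build_network()] result.
#' @param cfg a [run_config()] (supplies the reporting degree cutoff).
#' @return list of class `hub_pair`: `hub_S`, `hub_N`, `rho` (their
#'   correlation), `n_neg` of each, and whether the S hub exceeds the
#'   reporting cutoff scaled to the number of genera tested.
#' @export
find_hub_pair <- function(net, cfg = run_config()) {
  if (all(net$n_neg == 0)) {
    stop("no opposing structure: no correlation below rho_neg")
  }
  h1 <- net$genera[which.max(net$n_neg)]
  partner_rho <- net$rho[h1, ]
  partner_rho[h1] <- NA
  h2 <- net$genera[which.min(partner_rho)]
  pair_rho <- net$rho[h1, h2]
  if (!is.finite(pair_rho) || pair_rho >= net$rho_neg) {
    stop("no opposing structure: hub pair correlation above rho_neg")
  }
  ord <- order(net$n_neg[c(h1, h2)], decreasing = TRUE)
  hubs <- c(h1, h2)[ord]
  cutoff <- cfg$hub_degree_cutoff * length(net$genera) / 2387 # scale to cohort
  structure(list(hub_S = hubs[1], hub_N = hubs[2], rho = pair_rho,
                 n_neg = net$n_neg[hubs],
                 exceeds_cutoff = net$n_neg[hubs[1]] > cutoff),
            class = "hub_pair")
}

#' Assign genera to the two subnetworks
#'
#' A genus joins the N network iff `rho(., hub_N) > rho_pos` and
#' `rho(., hub_S) < rho_neg`; mirrored for the S network.  The two rules are
#' mutually exclusive, so the member sets are disjoint; genera satisfying
#' neither remain unassigned.
#'
#' @param net a [build_network()] result.
#' @param hubs a [find_hub_pair()] result.
#' @param cfg a [run_config()].
#' @return list of class `network_definition` with `hub_S`, `hub_N`,
#'   `members_S`, `members_N` and the thresholds used.
#' @export
assign_memberships <- function(net, hubs, cfg = run_config()) {
  rS <- net$rho[, hubs$hub_S]
  rN <- net$rho[, hubs$hub_N]
  g <- net$genera
  other <- setdiff(g, c(hubs$hub_S, hubs$hub_N))
  members_N <- other[rN[other] > cfg$rho_pos & rS[other] < cfg$rho_neg]
  members_S <- other[rS[other] > cfg$rho_pos & rN[other] < cfg$rho_neg]
  if (!length(members_N)) warning("N network has no members")
  if (!length(members_S)) warning("S network has no members")
  message(sprintf("assign_memberships: %d S members, %d N members, %d unassigned",
                  length(members_S), length(members_N),
                  length(other) - length(members_S) - length(members_N)))
  structure(list(hub_S = hubs$hub_S, hub_N = hubs$hub_N,
                 members_S = sort(members_S), members_N = sort(members_N),
                 rho_pos = cfg$rho_pos, rho_neg = cfg$rho_neg),
            class = "network_definition")
}

#' Per-sample summed network abundance
#'
#' @param gp a `genus_profile`.
#' @param nd a [assign_memberships()] result (or any list with `hub_S`,
#'   `hub_N`, `members_S`, `members_N`).
#' @return data.frame with `sample_id`, `abund_S`, `abund_N` in per mille.
#' @export
network_abundance <- function(gp, nd) {
  sum_block <- function(genera) {
    missing <- setdiff(genera, colnames(gp))
    if (length(missing)) {
      warning("network members absent from profile, skipped: ",
              paste(missing, collapse = ", "))
      genera <- setdiff(genera, missing)
    }
    rowSums(gp[, genera, drop = FALSE])
  }
  data.frame(sample_id = rownames(gp),
             abund_S = sum_block(c(nd$hub_S, nd$members_S)),
             abund_N = sum_block(c(nd$hub_N, nd$members_N)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Phylum enrichment between the two subnetworks
#'
#' For each phylum represented among network members, the 2x2 table
#' (in phylum vs not) x (S network vs N network) is summarised as an odds
#' ratio with Altman 95% confidence interval; OR > 1 means the phylum is
#' overrepresented in the S network.  Zero cells use the Haldane-Anscombe
#' +0.5 correction via [odds_ratio()].
#'
#' @param nd a [assign_memberships()] result.
#' @param phylum named vector mapping genus to phylum (e.g. the network's
#'   `phylum` field or the `genus_phylum` attribute of a profile).
#' @param include_hubs also count the hub genera themselves.
#' @return data.frame: phylum, counts in each network, OR, CI, corrected flag.
#' @export
phylum_enrichment <- function(nd, phylum, include_hubs = TRUE) {
  gS <- c(if (include_hubs) nd$hub_S, nd$members_S)
  gN <- c(if (include_hubs) nd$hub_N, nd$members_N)
  phS <- phylum[gS]
  phN <- phylum[gN]
  out <- lapply(sort(unique(c(phS, phN))), function(ph) {
    a <- sum(phS == ph, na.rm = TRUE)  # S network, in phylum
    b <- length(gS) - a
    cc <- sum(phN == ph, na.rm = TRUE) # N network, in phylum
    d <- length(gN) - cc
    if (a + cc == 0) return(NULL)
    or <- odds_ratio(a, b, cc, d)
    data.frame(phylum = ph, n_S = a, n_N = cc, or = or$or,
               ci_low = or$ci[1], ci_high = or$ci[2],
               corrected = or$corrected, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a network as edge-list and node TSV files
#'
#' Edges above `rho_pos` or below `rho_neg` are written as
#' `(genus_a, genus_b, rho, p, q)`; nodes as
#' `(genus, phylum, n_pos, n_neg, membership)`.
#'
#' @param net a [build_network()] result.
#' @param nd a [assign_memberships()] result.
#' @param edge_path,node_path output paths.
#' @export
write_network <- function(net, nd, edge_path, node_path) {
  ut <- which(upper.tri(net$rho) &
                (net$rho > net$rho_pos | net$rho < net$rho_neg), arr.ind = TRUE)
  edges <- data.frame(genus_a = net$genera[ut[, 1]],
                      genus_b = net$genera[ut[, 2]],
                      rho = net$rho[ut], p = net$p[ut], q = net$q[ut])
  write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  membership <- rep("unassigned", length(net$genera))
  names(membership) <- net$genera
  membership[nd$members_S] <- "S"
  membership[nd$members_N] <- "N"
  membership[nd$hub_S] <- "hub_S"
  membership[nd$hub_N] <- "hub_N"
  nodes <- data.frame(genus = net$genera,
                      phylum = if (is.null(net$phylum)) NA else net$phylum,
                      n_pos = net$n_pos, n_neg = net$n_neg,
                      membership = membership)
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(edges = nrow(edges), nodes = nrow(nodes)))
}
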