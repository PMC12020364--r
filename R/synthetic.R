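# Synthetic two-state sediment communities.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: each sample is in one of four latent states (S_only, N_only, both,
# neither); genus proportions are drawn from a state-conditional Dirichlet in
# which one hub genus plus its satellite block receives high concentration
# mass while the opposing block is suppressed; read counts are multinomial at
# a lognormal sequencing depth; nEQR is drawn from a state-conditional
# two-component beta mixture matched to P(nEQR < 0.8 | state); chemistry and
# macrofauna are coupled to the drawn block proportions.
#
# Because a Dirichlet block sum is Beta distributed, the asymptotic
# distribution of per-sample network abundance is an exact four-component
# Beta mixture; the generative antimode thresholds are computed analytically
# from that mixture, not from simulation.

#' Define a synthetic cohort scenario
#'
#' Defaults give a 600-sample, 200-genus cohort split 45/45/4/6% between a
#' sulfur-oxidizer-centred state, an ammonia-oxidizer-centred state, both and
#' neither, with overlapping low/high network-abundance modes (the bimodal
#' pattern the dip test targets) and deterioration probabilities yielding a
#' generative odds ratio near 11 for S-network presence.
#'
#' @param n_samples,n_genera cohort dimensions (genera excludes the two
#'   unclassified filler taxa added for aggregation realism).
#' @param hub_S,hub_N names of the two hub genera.
#' @param m_S,m_N satellite-set sizes of the S and N networks.
#' @param fractions named state probabilities (S_only, N_only, both,
#'   neither), summing to 1.
#' @param alpha per-state Dirichlet concentrations: a list with one entry per
#'   state, each `c(hub_S=, sat_S=, hub_N=, sat_N=, bg=)` giving the
#'   concentration of each hub, of every satellite in each block, and of every
#'   background genus.
#' @param p_det named P(nEQR < 0.8 | state).
#' @param depth_meanlog,depth_sdlog lognormal sequencing-depth parameters.
#' @param toc_effect shift of TOC (mg/g) per unit S-block proportion.
#' @param seed RNG seed.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_samples = 600L, n_genera = 200L,
                               hub_S = "Sulfurovum", hub_N = "Nitrosopumilus",
                               m_S = 10L, m_N = 50L,
                               fractions = c(S_only = 0.45, N_only = 0.45,
                                             both = 0.04, neither = 0.06),
                               alpha = list(
                                 S_only  = c(hub_S = 15,  sat_S = 1.4, hub_N = 0.9, sat_N = 0.10, bg = 0.174),
                                 N_only  = c(hub_S = 0.8, sat_S = 0.3, hub_N = 8,   sat_N = 0.50, bg = 0.145),
                                 both    = c(hub_S = 10,  sat_S = 1.2, hub_N = 7,   sat_N = 0.40, bg = 0.087),
                                 neither = c(hub_S = 1,   sat_S = 0.7, hub_N = 1,   sat_N = 0.18, bg = 0.29)
                               ),
                               p_det = c(S_only = 0.8, N_only = 0.2,
                                         both = 0.5, neither = 0.5),
                               depth_meanlog = log(5e4), depth_sdlog = 0.4,
                               toc_effect = 30, seed = 1L) {
  states <- c("S_only", "N_only", "both", "neither")
  stopifnot(setequal(names(fractions), states), setequal(names(p_det), states),
            setequal(names(alpha), states))
  fractions <- fractions[states]
  p_det <- p_det[states]
  if (abs(sum(fractions) - 1) > 1e-9) stop("state fractions must sum to 1")
  if (any(fractions < 0)) stop("state fractions must be non-negative")
  if (any(p_det < 0 | p_det > 1)) stop("p_det must be probabilities")
  if (m_S + m_N + 2L > n_genera) stop("m_S + m_N + 2 must not exceed n_genera")
  structure(list(n_samples = as.integer(n_samples),
                 n_genera = as.integer(n_genera), hub_S = hub_S, hub_N = hub_N,
                 m_S = as.integer(m_S), m_N = as.integer(m_N),
                 fractions = fractions, alpha = alpha, p_det = p_det,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 toc_effect = toc_effect, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# concentration vector over all internal taxa for one state
scenario_alpha_vec <- function(sc, state) {
  a <- sc$alpha[[state]]
  n_bg <- sc$n_genera - sc$m_S - sc$m_N - 2L
  c(a[["hub_S"]], rep(a[["sat_S"]], sc$m_S),
    a[["hub_N"]], rep(a[["sat_N"]], sc$m_N),
    rep(a[["bg"]], n_bg),
    rep(0.1, 2)) # two unclassified filler taxa, state-independent
}

scenario_taxa <- function(sc) {
  n_bg <- sc$n_genera - sc$m_S - sc$m_N - 2L
  genus <- c(sc$hub_S, sprintf("Sulfurovum_assoc_%02d", seq_len(sc$m_S)),
             sc$hub_N, sprintf("Nitrosopumilus_assoc_%02d", seq_len(sc$m_N)),
             sprintf("Background_%03d", seq_len(n_bg)),
             "unclassified", "unclassified")
  sat_S_phyla <- rep(c("Desulfobacterota", "Bacteroidota"),
                     length.out = sc$m_S)
  sat_N_phyla <- rep(c("Proteobacteria", "Proteobacteria", "Acidobacteriota",
                       "Planctomycetota", "Verrucomicrobiota"),
                     length.out = sc$m_N)
  bg_phyla <- rep(c("Proteobacteria", "Bacteroidota", "Chloroflexota",
                    "Actinobacteriota", "Firmicutes", "Planctomycetota"),
                  length.out = n_bg)
  phylum <- c("Campylobacterota", sat_S_phyla, "Crenarchaeota", sat_N_phyla,
              bg_phyla, "Proteobacteria", "unclassified")
  kingdom <- ifelse(phylum == "Crenarchaeota", "Archaea", "Bacteria")
  kingdom[genus == "unclassified"] <- c("Bacteria", "unclassified")
  data.frame(genus = genus, phylum = phylum, kingdom = kingdom,
             stringsAsFactors = FALSE)
}

# antimode (density minimum between the two largest modes) of a curve on a
# grid; refined location of the grid minimum between the two biggest peaks
curve_antimode <- function(grid, y) {
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) stop("mixture is not bimodal")
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  seg <- top2[1]:top2[2]
  grid[seg][which.min(y[seg])]
}

#' Analytic network-abundance mixture and antimode thresholds of a scenario
#'
#' The per-sample summed relative abundance of a network block under a
#' Dirichlet-multinomial community is (up to multinomial noise) Beta
#' distributed with shape `(alpha_block, alpha_total - alpha_block)`; across
#' states the cohort-level distribution is the corresponding four-component
#' Beta mixture.  Two antimodes are returned per network: the raw density
#' minimum of the mixture, and the minimum after convolution with a Gaussian
#' kernel at the deterministic Silverman bandwidth for `n_samples` draws --
#' the population functional targeted by the kernel-density estimator in
#' [antimode_threshold()], and therefore the generative ground truth used by
#' threshold-recovery checks.
#'
#' @param sc a [synthetic_scenario()].
#' @return list with `thr_S`, `thr_N` (smoothed, per mille) and `thr_S_raw`,
#'   `thr_N_raw`.
#' @export
scenario_antimodes <- function(sc) {
  states <- names(sc$fractions)
  grid <- seq(5e-4, 1 - 5e-4, length.out = 2000)
  step <- grid[2] - grid[1]
  out <- lapply(c(S = "S", N = "N"), function(net) {
    sh <- vapply(states, function(st) {
      a <- sc$alpha[[st]]
      tot <- sum(scenario_alpha_vec(sc, st))
      blk <- if (net == "S") a[["hub_S"]] + sc$m_S * a[["sat_S"]]
             else a[["hub_N"]] + sc$m_N * a[["sat_N"]]
      c(blk, tot - blk)
    }, numeric(2))
    w <- sc$fractions
    y <- rowSums(vapply(seq_along(w), function(i) {
      w[i] * stats::dbeta(grid, sh[1, i], sh[2, i])
    }, numeric(length(grid))))
    # mixture moments -> asymptotic nrd0 bandwidth
    mu <- sh[1, ] / colSums(sh)
    vv <- sh[1, ] * sh[2, ] / (colSums(sh)^2 * (colSums(sh) + 1))
    m1 <- sum(w * mu)
    sdev <- sqrt(sum(w * (vv + mu^2)) - m1^2)
    cdf <- cumsum(y) * step
    iqr <- grid[which.min(abs(cdf - 0.75))] - grid[which.min(abs(cdf - 0.25))]
    bw <- 0.9 * min(sdev, iqr / 1.34) * sc$n_samples^(-1 / 5)
    ys <- vapply(grid, function(g) {
      k <- stats::dnorm(grid, g, bw)
      sum(y * k) * step
    }, 0)
    list(smooth = 1000 * curve_antimode(grid, ys),
         raw = 1000 * curve_antimode(grid, y))
  })
  list(thr_S = out$S$smooth, thr_N = out$N$smooth,
       thr_S_raw = out$S$raw, thr_N_raw = out$N$raw)
}

#' Closed-form deterioration odds ratio of a scenario
#'
#' The odds ratio for `nEQR < 0.8` given presence of a network, computed
#' analytically from the state fractions and the per-state deterioration
#' probabilities.  Degenerate probabilities (0 or 1 in either arm) give an
#' infinite or zero odds ratio, with a warning.
#'
#' @param sc a [synthetic_scenario()].
#' @param exposure `"S"` (states S_only/both are exposed) or `"N"`.
#' @return the generative odds ratio (possibly `Inf` or 0).
#' @export
generative_odds_ratio <- function(sc, exposure = c("S", "N")) {
  exposure <- match.arg(exposure)
  exposed <- if (exposure == "S") c("S_only", "both") else c("N_only", "both")
  f <- sc$fractions
  p <- sc$p_det
  w1 <- f[exposed] / sum(f[exposed])
  w0 <- f[setdiff(names(f), exposed)] / sum(f[setdiff(names(f), exposed)])
  p1 <- sum(w1 * p[exposed])
  p0 <- sum(w0 * p[setdiff(names(f), exposed)])
  if (p1 %in% c(0, 1) || p0 %in% c(0, 1)) {
    warning("degenerate deterioration probability; odds ratio is 0 or Inf")
    return(if (p1 == 1 || p0 == 0) Inf else 0)
  }
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (OTU counts, taxonomy, metadata, macrofauna) from a
#' scenario, together with the generative ground truth used by recovery
#' tests.  Fully reproducible: the same scenario (including its seed) yields
#' an identical cohort, and the caller's RNG state is left untouched.
#'
#' A little aggregation realism is built in: five background genera are split
#' across two OTUs each and two filler taxa carry an unclassified genus, so
#' [aggregate_to_genus()] has real work to do.
#'
#' @param sc a [synthetic_scenario()].
#' @return list of class `synthetic_cohort` with elements `counts`
#'   ([count_table()], OTU level), `taxonomy` ([taxonomy_map()]), `metadata`
#'   ([read_sample_metadata()] format), `macrofauna` ([macrofauna_table()])
#'   and `truth` (state per sample, network memberships, generative
#'   thresholds and odds ratios).
#' @export
generate_cohort <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  taxa <- scenario_taxa(sc)
  n_taxa <- nrow(taxa)
  n <- sc$n_samples
  states <- names(sc$fractions)
  alpha_mat <- vapply(states, function(st) scenario_alpha_vec(sc, st),
                      numeric(n_taxa))

  i_S <- seq_len(1 + sc$m_S)                        # hub_S plus its satellites
  i_N <- seq(2 + sc$m_S, 2 + sc$m_S + sc$m_N)       # hub_N plus its satellites

  with_seed(sc$seed, {
    state <- sample(states, n, replace = TRUE, prob = sc$fractions)
    depth <- pmax(1000, round(rlnorm(n, sc$depth_meanlog, sc$depth_sdlog)))
    counts <- matrix(0L, n, n_taxa)
    pS <- pN <- numeric(n)
    for (i in seq_len(n)) {
      prop <- rdirichlet1(alpha_mat[, state[i]])
      pS[i] <- sum(prop[i_S])
      pN[i] <- sum(prop[i_N])
      counts[i, ] <- rmultinom(1, depth[i], prop)[, 1]
    }
    sample_id <- sprintf("sample_%04d", seq_len(n))
    rownames(counts) <- sample_id

    # nEQR: deterioration flag matched exactly to P(det | state), value from
    # a scaled beta on the corresponding side of the 0.8 cutoff
    det <- rbinom(n, 1, sc$p_det[state]) == 1
    neqr <- ifelse(det, 0.8 * rbeta(n, 6, 2), 0.8 + 0.2 * rbeta(n, 2, 2))

    metadata <- data.frame(
      sample_id = sample_id,
      neqr = neqr,
      depth = runif(n, 30, 350),
      distance = exp(log(2000) - 1.8 * pS + rnorm(n, 0, 0.6)),
      toc = 12 + sc$toc_effect * pS + rnorm(n, 0, 4),
      total_n = 2 + 3 * pS + rnorm(n, 0, 0.8),
      ph = 7.9 - 0.8 * pS + rnorm(n, 0, 0.15),
      redox = 150 - 350 * pS + rnorm(n, 0, 60),
      pelite = stats::plogis(-0.4 + 1.5 * pN + rnorm(n, 0, 0.5)),
      cu = rlnorm(n, log(20) + 0.8 * pS, 0.4),
      zn = rlnorm(n, log(80) + 0.6 * pN, 0.3),
      region = ifelse(runif(n) < ifelse(state %in% c("S_only", "both"), 0.35, 0.05),
                      "iceland",
                      sample(c("north_sea", "mid_norway", "north_norway"), n, TRUE)),
      investigation_type = ifelse(runif(n) < ifelse(state == "N_only", 0.5, 0.15),
                                  "pre_examination",
                                  sample(c("b_investigation", "c_investigation"), n, TRUE)),
      stringsAsFactors = FALSE
    )

    # macrofauna: 5 taxa per AMBI tolerance group; sensitive groups (0-2)
    # thrive where the N block dominates, opportunists (5-6) with the S block
    groups <- rep(0:6, each = 5)
    mf_taxa <- sprintf("mf_g%d_t%d", groups, sequence(rep(5, 7)))
    z <- pS - pN
    lambda <- exp(outer(z, (groups / 3 - 1) * 3) + 1.2)
    mf <- matrix(rpois(length(lambda), lambda), n,
                 dimnames = list(sample_id, mf_taxa))

    # OTU table: one OTU per taxon, except five background genera split in two
    split_idx <- which(startsWith(taxa$genus, "Background"))[1:5]
    otu_counts <- counts
    otu_tax <- taxa
    for (k in split_idx) {
      extra <- rbinom(n, counts[, k], 0.5)
      otu_counts[, k] <- counts[, k] - extra
      otu_counts <- cbind(otu_counts, extra)
      otu_tax <- rbind(otu_tax, taxa[k, ])
    }
    otu_id <- sprintf("otu_%04d", seq_len(ncol(otu_counts)))
    colnames(otu_counts) <- otu_id
  })

  taxonomy <- taxonomy_map(data.frame(
    taxon_id = otu_id, kingdom = otu_tax$kingdom, phylum = otu_tax$phylum,
    genus = otu_tax$genus, stringsAsFactors = FALSE))

  # degenerate (single-state) scenarios have no bimodal mixture and hence no
  # generative thresholds
  thr <- tryCatch(scenario_antimodes(sc), error = function(e) {
    list(thr_S = NA_real_, thr_N = NA_real_,
         thr_S_raw = NA_real_, thr_N_raw = NA_real_)
  })
  truth <- list(
    state = setNames(state, sample_id),
    hub_S = sc$hub_S, hub_N = sc$hub_N,
    members_S = taxa$genus[i_S[-1]],
    members_N = taxa$genus[i_N[-1]],
    thr_S = thr$thr_S, thr_N = thr$thr_N,
    thr_S_raw = thr$thr_S_raw, thr_N_raw = thr$thr_N_raw,
    or_S = generative_odds_ratio(sc, "S"),
    or_N = generative_odds_ratio(sc, "N"),
    pS = setNames(1000 * pS, sample_id),
    pN = setNames(1000 * pN, sample_id)
  )

  structure(list(counts = count_table(otu_counts),
                 taxonomy = taxonomy,
                 metadata = sample_metadata(metadata),
                 macrofauna = macrofauna_table(mf, setNames(as.integer(groups), mf_taxa)),
                 truth = truth, scenario = sc),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(dir, "counts.tsv"))
  write.table(cohort$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- data.frame(sample_id = rownames(cohort$macrofauna$abundance),
                   cohort$macrofauna$abundance, check.names = FALSE)
  write.table(mf, file.path(dir, "macrofauna.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon_id = names(cohort$macrofauna$tolerance),
                         tolerance_group = cohort$macrofauna$tolerance),
              file.path(dir, "macrofauna_tolerance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  write.table(data.frame(sample_id = names(tr$state), state = tr$state,
                         pS_permille = tr$pS, pN_permille = tr$pN),
              file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
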