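# End-to-end orchestration: ingest -> network -> binarize -> risk ->
# diversity -> GAM, with a machine-readable run manifest.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis
#'
#' Executes all stages in dependency order on a cohort read from `input_dir`
#' (as written by [write_cohort()] or assembled externally in the same
#' layout) and writes every stage output plus a JSON run manifest to
#' `output_dir`.  The macrofauna stage is skipped, with a log line, when the
#' macrofauna tables are absent.  All stochastic stages derive their seeds
#' from `cfg$seed`, so a rerun with the same inputs and config is
#' reproducible.
#'
#' @param input_dir directory with `counts.tsv`, `taxonomy.tsv`,
#'   `metadata.tsv` and optionally `macrofauna.tsv` +
#'   `macrofauna_tolerance.tsv`.
#' @param output_dir output directory (created).
#' @param cfg a [run_config()] or path to a key=value config file.
#' @return the manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_all <- function(input_dir, output_dir, cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  message("run_all config: ",
          paste(names(cfg), vapply(cfg, format, ""), sep = "=", collapse = " "))
  outputs <- list()
  stage <- function(name, expr) {
    message("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # ingest
  ct <- stage("ingest", read_count_table(file.path(input_dir, "counts.tsv")))
  tax <- read_taxonomy(file.path(input_dir, "taxonomy.tsv"))
  meta <- read_sample_metadata(file.path(input_dir, "metadata.tsv"))
  gt <- stage("aggregate", aggregate_to_genus(ct, tax))
  if (isTRUE(cfg$exclude_chloroplast)) {
    chl <- grepl("[Cc]hloroplast", attr(gt, "genus_phylum")[colnames(gt)])
    gt <- count_table(unclass(gt)[, !chl, drop = FALSE])
  }
  gp <- to_relative_permille(gt)

  # network
  net <- stage("network", build_network(gp, cfg))
  hubs <- stage("network", find_hub_pair(net, cfg))
  nd <- assign_memberships(net, hubs, cfg)
  na <- network_abundance(gp, nd)
  outputs$network_edges <- write_tsv_network(net, nd, output_dir)
  outputs$network_abundance <- write_tsv(na, file.path(output_dir, "network_abundance.tsv"))
  enr <- phylum_enrichment(nd, net$phylum)
  outputs$phylum_enrichment <- write_tsv(enr, file.path(output_dir, "phylum_enrichment.tsv"))

  # binarize
  dip_S <- stage("binarize", dip_test(na$abund_S, B = cfg$dip_replicates,
                                      seed = cfg$seed + 1L, alpha = cfg$dip_alpha))
  dip_N <- dip_test(na$abund_N, B = cfg$dip_replicates,
                    seed = cfg$seed + 2L, alpha = cfg$dip_alpha)
  thr_S <- if (dip_S$significant) antimode_threshold(na$abund_S, dip_S)$threshold else NA
  thr_N <- if (dip_N$significant) antimode_threshold(na$abund_N, dip_N)$threshold else NA
  st <- assign_states(na, thr_S, thr_N, meta, cfg)
  outputs$state_table <- write_tsv(st, file.path(output_dir, "state_table.tsv"))
  dip_report <- data.frame(
    network = c("S", "N"),
    dip = c(dip_S$dip, dip_N$dip), p_value = c(dip_S$p_value, dip_N$p_value),
    threshold_permille = c(thr_S, thr_N),
    modal_lo = c(dip_S$modal_lo, dip_N$modal_lo),
    modal_hi = c(dip_S$modal_hi, dip_N$modal_hi))
  outputs$dip_report <- write_tsv(dip_report, file.path(output_dir, "dip_report.tsv"))

  # risk & associations
  assoc <- list()
  if (!all(is.na(st$deteriorated))) {
    for (expo in c("S_present", "N_present")) {
      r <- stage("risk", deterioration_risk(st, expo))
      assoc[[expo]] <- data.frame(analysis = "deterioration_or", unit = expo,
                                  estimate = r$or, ci_low = r$ci[1],
                                  ci_high = r$ci[2], p = NA, q = NA,
                                  n = r$n_used)
    }
  } else {
    message("risk stage skipped: no nEQR in metadata")
  }
  for (netw in c("S", "N")) {
    ca <- covariate_association(na, meta, network = netw)
    assoc[[paste0("cov_", netw)]] <-
      data.frame(analysis = paste0("covariate_rho_", netw), unit = ca$field,
                 estimate = ca$rho, ci_low = NA, ci_high = NA, p = ca$p,
                 q = ca$q, n = ca$n)
  }
  mf_path <- file.path(input_dir, "macrofauna.tsv")
  tol_path <- file.path(input_dir, "macrofauna_tolerance.tsv")
  if (file.exists(mf_path) && file.exists(tol_path)) {
    mf <- read_macrofauna(mf_path, tol_path)
    for (netw in c("S", "N")) {
      tp <- stage("risk", tolerance_profile(na, mf, netw))
      assoc[[paste0("tol_", netw)]] <-
        data.frame(analysis = paste0("tolerance_rho_", netw),
                   unit = as.character(tp$tolerance_group), estimate = tp$rho,
                   ci_low = NA, ci_high = NA, p = tp$p, q = tp$q, n = tp$n)
    }
  } else {
    message("tolerance-profile stage skipped: macrofauna tables absent")
  }
  outputs$associations <- write_tsv(do.call(rbind, assoc),
                                    file.path(output_dir, "associations.tsv"))

  # diversity & ordination
  div <- stage("diversity", alpha_diversity(gp))
  outputs$alpha_diversity <- write_tsv(div, file.path(output_dir, "alpha_diversity.tsv"))
  bc <- bray_curtis(gp)
  ord <- pcoa_ordination(bc)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates[, seq_len(min(4, ncol(ord$coordinates))),
                                       drop = FALSE],
                       state = st$state[match(rownames(ord$coordinates),
                                              st$sample_id)])
  outputs$pcoa <- write_tsv(coords, file.path(output_dir, "pcoa_coordinates.tsv"))

  # GAM
  gam_res <- NULL
  if (!all(is.na(st$neqr))) {
    gdat <- data.frame(neqr = st$neqr, abund_S = st$abund_S,
                       abund_N = st$abund_N,
                       depth = meta$depth[match(st$sample_id, meta$sample_id)],
                       distance = meta$distance[match(st$sample_id, meta$sample_id)])
    gam_res <- stage("gam", fit_gam_cv(gdat, cfg = cfg))
    outputs$gam_cv <- write_tsv(
      data.frame(sample_id = st$sample_id[as.integer(rownames(gam_res$data))],
                 observed = gam_res$observed, cv_pred = gam_res$cv_pred,
                 fold = gam_res$folds),
      file.path(output_dir, "gam_cv_predictions.tsv"))
    pd_all <- do.call(rbind, lapply(gam_res$components, function(cmp) {
      pd <- partial_dependence(gam_res, cmp)
      data.frame(component = cmp, grid = pd$grid, pd = pd$pd)
    }))
    outputs$gam_pd <- write_tsv(pd_all, file.path(output_dir, "gam_partial_dependence.tsv"))
  } else {
    message("gam stage skipped: no nEQR in metadata")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("benthicnet")),
    config = unclass(cfg),
    inputs = input_hashes(input_dir),
    stages = list(
      ingest = list(n_samples = nrow(ct), n_taxa = ncol(ct),
                    n_genera = ncol(gt)),
      network = list(n_genera_tested = length(net$genera),
                     n_filtered = net$n_filtered,
                     hub_S = nd$hub_S, hub_N = nd$hub_N,
                     hub_rho = hubs$rho,
                     n_members_S = length(nd$members_S),
                     n_members_N = length(nd$members_N)),
      binarize = list(dip_S = dip_S$dip, dip_N = dip_N$dip,
                      p_S = dip_S$p_value, p_N = dip_N$p_value,
                      thr_S = thr_S, thr_N = thr_N,
                      states = as.list(table(st$state))),
      gam = if (!is.null(gam_res)) list(cv_rho = gam_res$cv_rho,
                                        cv_rmse = gam_res$cv_rmse)
    ),
    outputs = lapply(outputs, basename)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv_network <- function(net, nd, output_dir) {
  write_network(net, nd,
                file.path(output_dir, "network_edges.tsv"),
                file.path(output_dir, "network_nodes.tsv"))
  file.path(output_dir, "network_edges.tsv")
}

input_hashes <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  as.list(setNames(unname(tools::md5sum(files)), basename(files)))
}

#' Simulate a cohort to disk
#'
#' Thin wrapper chaining [synthetic_scenario()], [generate_cohort()] and
#' [write_cohort()]; the scenario may be given as a key=value file with the
#' scalar scenario fields (`n_samples`, `n_genera`, `m_S`, `m_N`, `seed`,
#' `toc_effect`, ...).
#'
#' @param dir output directory.
#' @param scenario a [synthetic_scenario()], or path to a scenario file, or
#'   `NULL` for the default scenario.
#' @return the directory, invisibly.
#' @export
simulate_cohort <- function(dir, scenario = NULL) {
  sc <- if (is.null(scenario)) {
    synthetic_scenario()
  } else if (is.character(scenario)) {
    lines <- readLines(scenario)
    lines <- sub("#.*", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- strsplit(lines, "\\s*=\\s*")
    args <- lapply(kv, function(p) {
      v <- p[2]
      if (grepl("^-?[0-9.eE+-]+$", v)) as.numeric(v) else v
    })
    names(args) <- vapply(kv, `[`, "", 1L)
    bad <- setdiff(names(args), names(formals(synthetic_scenario)))
    if (length(bad)) stop("unknown scenario key(s): ", paste(bad, collapse = ", "))
    do.call(synthetic_scenario, args)
  } else {
    scenario
  }
  write_cohort(generate_cohort(sc), dir)
}
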