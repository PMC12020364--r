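# Tabular input/output and the pipeline's domain types.
#
# All tables are tab-separated UTF-8 with a header row and ids in the first
# column.  Counts are samples x taxa matrices of non-negative integers;
# relative abundance is expressed in per mille of the per-sample total.

#' Construct and validate a count table
#'
#' A count table is a samples-by-taxa matrix of non-negative integer read
#' counts with unique sample and taxon identifiers.  Row sums may differ:
#' unequal sequencing depth is expected and handled downstream by
#' [to_relative_permille()].
#'
#' @param counts numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids,taxon_ids character vectors; default to dimnames.
#' @return A `count_table`: an integer matrix with class attribute.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(taxon_ids)) {
    stop("count_table requires sample and taxon ids")
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("count_table requires at least 2 samples and 2 taxa")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon id(s): ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)
    if (length(bad)) {
      stop("non-numeric count at row '", sample_ids[bad[1, 1]],
           "', column '", taxon_ids[bad[1, 2]], "'")
    }
    stop("counts must be numeric")
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)
    stop("negative count at row '", sample_ids[bad[1, 1]],
         "', column '", taxon_ids[bad[1, 2]], "'")
  }
  storage.mode(counts) <- "double"
  if (any(counts != round(counts))) {
    stop("counts must be integers")
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  class(counts) <- c("count_table", "matrix", "array")
  counts
}

#' Read a count table from a TSV file
#'
#' @param path file path.
#' @param format `"tsv"` (plain) or `"biom-tsv"` (a `#` comment line and an
#'   `#OTU ID` header, taxa in rows, as written by BIOM text exports).
#' @param orientation `"samples"` if samples are rows, `"taxa"` if taxa are
#'   rows (the matrix is transposed to samples x taxa).  Ignored for
#'   `biom-tsv`, which is always taxa-in-rows.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-tsv"),
                             orientation = c("samples", "taxa")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = if (format == "biom-tsv") "" else "#",
                   skip = if (format == "biom-tsv") {
                     if (startsWith(readLines(path, n = 1L), "# ")) 1L else 0L
                   } else 0L,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric cell in '", path, "' at id '", ids[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "'")
  }
  rownames(m) <- ids
  if (format == "biom-tsv" || orientation == "taxa") m <- t(m)
  ct <- count_table(m)
  message(sprintf("read_count_table: %d samples x %d taxa from %s",
                  nrow(ct), ncol(ct), path))
  ct
}

#' Write a count table as TSV (samples in rows)
#'
#' @param ct a [count_table()].
#' @param path output path.
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(sample_id = rownames(ct), unclass(ct),
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct a taxonomy map
#'
#' Maps taxon ids to RDP-style ranks kingdom..genus.  Missing ranks are the
#' sentinel `"unclassified"`.
#'
#' @param df data.frame with column `taxon_id` plus any of kingdom, phylum,
#'   class, order, family, genus.
#' @return A `taxonomy_map` data.frame with all six rank columns.
#' @export
taxonomy_map <- function(df) {
  if (!"taxon_id" %in% names(df)) stop("taxonomy requires a taxon_id column")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy")
  for (r in RANKS) {
    if (!r %in% names(df)) df[[r]] <- "unclassified"
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]]) | df[[r]] == ""] <- "unclassified"
  }
  df <- df[, c("taxon_id", RANKS)]
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a taxonomy TSV (taxon_id + rank columns)
#' @param path file path.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  taxonomy_map(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Read sample metadata
#'
#' Expected columns (all optional except `sample_id`): `neqr` in \[0,1\],
#' `depth` (m), `distance` (m, to nearest aquaculture site), `toc` (mg/g),
#' `total_n` (mg/kg), `ph`, `redox` (mV), `pelite` (fraction), `cu`, `zn`
#' (mg/kg), `region`, `investigation_type`.  Empty strings and `NA` are
#' missing values and are preserved, never imputed.
#'
#' @param path file path.
#' @return data.frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df data.frame with a `sample_id` column.
#' @export
sample_metadata <- function(df) {
  if (!"sample_id" %in% names(df)) stop("metadata requires sample_id")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if ("neqr" %in% names(df)) {
    bad <- !is.na(df$neqr) & (df$neqr < 0 | df$neqr > 1)
    if (any(bad)) {
      stop("nEQR outside [0,1] for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "))
    }
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read a macrofauna abundance table plus AMBI tolerance groups
#'
#' @param abundance_path samples x macrofauna-taxa TSV (samples in rows).
#' @param tolerance_path two-column TSV `taxon_id`, `tolerance_group`
#'   (integer 0-6; missing group leaves the taxon flagged unassigned).
#' @return list of class `macrofauna_table` with elements `abundance`
#'   (matrix) and `tolerance` (named integer vector, `NA` = unassigned).
#' @export
read_macrofauna <- function(abundance_path, tolerance_path) {
  ab <- read.delim(abundance_path, sep = "\t", check.names = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- as.character(ab[[1]])
  tg <- read.delim(tolerance_path, sep = "\t", stringsAsFactors = FALSE)
  macrofauna_table(m, setNames(as.integer(tg$tolerance_group), tg$taxon_id))
}

#' @rdname read_macrofauna
#' @param abundance samples x taxa abundance matrix.
#' @param tolerance named integer vector of AMBI groups (0-6).
#' @export
macrofauna_table <- function(abundance, tolerance) {
  if (any(abundance < 0)) stop("macrofauna abundances must be non-negative")
  known <- !is.na(tolerance)
  if (any(!tolerance[known] %in% 0:6)) {
    stop("tolerance groups must be integers 0..6")
  }
  missing <- setdiff(colnames(abundance), names(tolerance))
  if (length(missing)) {
    tolerance <- c(tolerance, setNames(rep(NA_integer_, length(missing)), missing))
    message("macrofauna_table: ", length(missing),
            " taxa without tolerance group flagged unassigned")
  }
  structure(list(abundance = abundance, tolerance = tolerance),
            class = "macrofauna_table")
}

#' Pipeline run configuration
#'
#' Holds every tunable of the analysis.  Defaults follow the published
#' analysis: correlation thresholds +/-0.3, 10,000 dip bootstrap replicates,
#' dip alpha 0.05, nEQR deterioration cutoff 0.8, 10 GAM folds,
#' Benjamini-Hochberg FDR.  The hub degree cutoff (500 strong negative edges
#' in the original cohort) is a reporting threshold, scaled here to the
#' number of genera tested; hub selection itself uses the maximum count.
#'
#' @param rho_pos,rho_neg positive/negative Spearman correlation thresholds.
#' @param hub_degree_cutoff reported degree threshold for hub candidacy.
#' @param dip_replicates bootstrap replicates for the dip test (>= 100).
#' @param dip_alpha significance level for the dip test.
#' @param neqr_cutoff nEQR below this value is "deteriorated".
#' @param gam_folds cross-validation folds (>= 2).
#' @param gam_knots basis dimension per smooth term.
#' @param fdr_method multiple-testing correction (only `"BH"` supported).
#' @param prevalence_min,abundance_min prevalence filter before correlation:
#'   keep genera detected in at least this fraction of samples and with at
#'   least this mean per-mille abundance.  Set both to 0 for full-cohort mode.
#' @param use_clr use a centred log-ratio transform before correlation
#'   (off by default; the published analysis correlates per-mille values).
#' @param exclude_chloroplast drop chloroplast/organelle genera before
#'   normalisation (off by default; they are part of the community total).
#' @param seed RNG seed used by stochastic stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(rho_pos = 0.3, rho_neg = -0.3, hub_degree_cutoff = 500,
                       dip_replicates = 10000, dip_alpha = 0.05,
                       neqr_cutoff = 0.8, gam_folds = 10, gam_knots = 10,
                       fdr_method = "BH", prevalence_min = 0.05,
                       abundance_min = 0.1, use_clr = FALSE,
                       exclude_chloroplast = FALSE, seed = 1L) {
  stopifnot(rho_neg < 0, 0 < rho_pos, dip_replicates >= 100, gam_folds >= 2,
            fdr_method == "BH", dip_alpha > 0, dip_alpha < 1)
  structure(list(rho_pos = rho_pos, rho_neg = rho_neg,
                 hub_degree_cutoff = hub_degree_cutoff,
                 dip_replicates = as.integer(dip_replicates),
                 dip_alpha = dip_alpha, neqr_cutoff = neqr_cutoff,
                 gam_folds = as.integer(gam_folds),
                 gam_knots = as.integer(gam_knots), fdr_method = fdr_method,
                 prevalence_min = prevalence_min,
                 abundance_min = abundance_min, use_clr = use_clr,
                 exclude_chloroplast = exclude_chloroplast,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key=value config file into a [run_config()]
#' @param path file path; lines `key = value`, `#` comments allowed.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- names(formals(run_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    if (v %in% c("TRUE", "FALSE", "true", "false")) {
      toupper(v) == "TRUE"
    } else if (grepl("^-?[0-9.eE+-]+$", v)) {
      as.numeric(v)
    } else {
      v
    }
  })
  names(args) <- keys
  do.call(run_config, args)
}

#' Aggregate an OTU-level count table to genus level
#'
#' Every taxon is routed to its genus; taxa whose genus is unclassified go to
#' a per-phylum bucket `unclassified_<phylum>` (falling back to kingdom) so
#' that total counts are conserved.  Bucket columns are retained for
#' normalisation but are not biological genera; [build_network()] excludes
#' them from hub candidacy.
#'
#' @param ct a [count_table()] of OTUs.
#' @param tax a [taxonomy_map()].
#' @return A genus-level [count_table()] with attribute `genus_phylum`,
#'   a named vector giving the majority phylum of each output column.
#' @export
aggregate_to_genus <- function(ct, tax) {
  idx <- match(colnames(ct), tax$taxon_id)
  if (all(is.na(idx))) stop("no taxa of the count table occur in the taxonomy")
  genus <- ifelse(is.na(idx), "unclassified", tax$genus[idx])
  phylum <- ifelse(is.na(idx), "unclassified", tax$phylum[idx])
  kingdom <- ifelse(is.na(idx), "unclassified", tax$kingdom[idx])
  bucketed <- genus == "unclassified"
  parent <- ifelse(phylum != "unclassified", phylum, kingdom)
  genus[bucketed] <- paste0("unclassified_", parent[bucketed])
  out <- rowsum(t(unclass(ct)), group = genus)
  gt <- count_table(t(out))
  gp <- vapply(split(phylum, genus), function(p) names(sort(table(p),
                                                            decreasing = TRUE))[1], "")
  attr(gt, "genus_phylum") <- gp[colnames(gt)]
  attr(gt, "bucket") <- setNames(startsWith(colnames(gt), "unclassified"),
                                 colnames(gt))
  stopifnot(sum(gt) == sum(ct)) # conservation of counts
  message(sprintf("aggregate_to_genus: %d taxa -> %d genus-level columns (%d buckets)",
                  ncol(ct), ncol(gt), sum(attr(gt, "bucket"))))
  gt
}

#' Convert counts to per-mille relative abundance
#'
#' @param ct a [count_table()] (typically genus-level).
#' @return A `genus_profile`: samples x taxa matrix whose rows each sum to
#'   1000 (per mille).  Carries over `genus_phylum`/`bucket` attributes.
#' @export
to_relative_permille <- function(ct) {
  rs <- rowSums(ct)
  if (any(rs == 0)) {
    stop("zero-sum sample(s): ", paste(rownames(ct)[rs == 0], collapse = ", "))
  }
  gp <- 1000 * unclass(ct) / rs
  attr(gp, "genus_phylum") <- attr(ct, "genus_phylum")
  attr(gp, "bucket") <- attr(ct, "bucket")
  class(gp) <- c("genus_profile", "matrix", "array")
  gp
}
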