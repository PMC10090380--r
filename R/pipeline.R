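# End-to-end concordance runs: trees + manifest in, per-gene RF table,
# per-set summaries, baseline model and run log out.

#' Pipeline configuration
#'
#' @param reference_tree path to the reference species tree (Newick).
#' @param manifest path to a TSV with columns `gene_id`, `tree_path`,
#'   `set_label` and optionally `alignment_path`; relative paths are
#'   resolved against the manifest's directory.
#' @param reference_set gene-set label used as the background for
#'   relative RF statistics (default `"sOG"`).
#' @param bin_size,quantile,remainder_policy baseline-fit settings, see
#'   [fit_pis_baseline()].
#' @param polytomy_threshold exclusion threshold, see
#'   [apply_exclusion()].
#' @param epsilon baseline validity guard, see [normalize_rf()].
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV.
#' @return a `run_config` list.
#' @export
run_config <- function(reference_tree, manifest, reference_set = "sOG",
                       bin_size = 1000L, quantile = 0.05,
                       remainder_policy = "merge",
                       polytomy_threshold = 0.5, epsilon = 1e-6,
                       out_dir = NULL) {
  for (p in c(reference_tree, manifest))
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  assert_scalar_number(bin_size, "bin_size", 1)
  assert_scalar_number(quantile, "quantile", 1e-12, 1)
  assert_scalar_number(polytomy_threshold, "polytomy_threshold", 0, 1)
  structure(list(reference_tree = reference_tree, manifest = manifest,
                 reference_set = reference_set,
                 bin_size = as.integer(bin_size), quantile = quantile,
                 remainder_policy = remainder_policy,
                 polytomy_threshold = polytomy_threshold,
                 epsilon = epsilon, out_dir = out_dir),
            class = "run_config")
}

read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tree_path", "set_label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$gene_id))
    stop("duplicate gene_id in manifest", call. = FALSE)
  if (!"alignment_path" %in% names(man)) man$alignment_path <- NA_character_
  man
}

resolve_path <- function(p, base) {
  ifelse(is.na(p) | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
}

#' Run the full concordance analysis
#'
#' For every gene in the manifest: read its tree, compute the RF record
#' against the reference tree (pruning to shared tips), apply the
#' polytomy exclusion rule, and (when alignments are provided) count
#' parsimony-informative sites. A PIS baseline is then fitted over all
#' included records and every RF value is divided by its fitted
#' baseline. Gene sets are summarized on both scales, with relative RF
#' against the configured reference set.
#'
#' @param config a [run_config()].
#' @return a list of class `concordance_run`:
#'   \describe{
#'     \item{records}{per-gene RF table (one row per manifest entry),
#'       with `rf_prime` where normalization applied.}
#'     \item{summaries}{per-set table with mean/sd of `norm_rf` and of
#'       `rf_prime`, plus `relative_rf` and `relative_rf_prime` versus
#'       the reference set.}
#'     \item{model}{the fitted `pis_baseline`, or NULL when no
#'       alignments were available.}
#'     \item{log}{parameter echo and exclusion counts.}
#'   }
#'   When `config$out_dir` is set, `records.tsv`, `summaries.tsv`,
#'   `model.tsv` and `run_log.tsv` are also written there with numbers
#'   fixed to 6 significant digits (re-runs are byte-identical).
#' @export
run_concordance <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ref <- read_newick_file(config$reference_tree)[[1L]]
  man <- read_manifest(config$manifest)
  base_dir <- dirname(config$manifest)
  tree_paths <- resolve_path(man$tree_path, base_dir)
  aln_paths <- resolve_path(man$alignment_path, base_dir)

  missing <- !file.exists(tree_paths)
  if (any(missing))
    stop("missing gene tree file(s) for: ",
         paste(man$gene_id[missing], collapse = ", "), call. = FALSE)

  records <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    gt <- read_newick_file(tree_paths[i])[[1L]]
    rec <- tryCatch(
      rf_distance(gt, ref, gene_id = man$gene_id[i]),
      error = function(e) {
        r <- rf_record_row(gene_id = man$gene_id[i],
                           excluded = TRUE,
                           reason = "insufficient_overlap")
        r$polytomy_fraction <- polytomy_tip_fraction(gt)
        r
      })
    if (!is.na(aln_paths[i]) && nzchar(aln_paths[i])) {
      if (!file.exists(aln_paths[i]))
        stop("missing alignment file for gene ", man$gene_id[i],
             call. = FALSE)
      rec$n_pis <- count_pis(read_alignment(aln_paths[i]))$n_pis
    }
    records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  records$set_label <- man$set_label
  records <- apply_exclusion(records, threshold = config$polytomy_threshold)

  model <- NULL
  records$rf_prime <- NA_real_
  fit_ok <- !records$excluded & !is.na(records$n_pis) & records$n_pis >= 1L
  if (sum(fit_ok) >= 2L &&
      length(unique(records$n_pis[fit_ok])) >= 2L) {
    model <- fit_pis_baseline(records, bin_size = config$bin_size,
                              quantile = config$quantile,
                              remainder_policy = config$remainder_policy)
    records$rf_prime[fit_ok] <- normalize_rf(records$norm_rf[fit_ok],
                                             records$n_pis[fit_ok], model,
                                             epsilon = config$epsilon)
  } else if (any(!is.na(records$n_pis))) {
    warning("too few usable PIS records; baseline normalization skipped",
            call. = FALSE)
  }

  sets <- unique(man$set_label)
  summaries <- do.call(rbind, lapply(sets, function(set) {
    sub <- records[records$set_label == set, , drop = FALSE]
    if (all(sub$excluded)) {
      warning("gene set \"", set, "\" has no included trees", call. = FALSE)
      return(data.frame(set_label = set, n_trees = 0L, mean_rf = NA_real_,
                        sd_rf = NA_real_, sd_undefined = NA,
                        mean_rf_prime = NA_real_, sd_rf_prime = NA_real_,
                        stringsAsFactors = FALSE))
    }
    s <- summarize_gene_set(sub, set)
    if (!is.null(model) && any(!is.na(sub$rf_prime) & !sub$excluded)) {
      sp <- summarize_gene_set(sub, set, value = "rf_prime")
      s$mean_rf_prime <- sp$mean_rf
      s$sd_rf_prime <- sp$sd_rf
    } else {
      s$mean_rf_prime <- NA_real_
      s$sd_rf_prime <- NA_real_
    }
    s
  }))

  ref_row <- summaries[summaries$set_label == config$reference_set, ]
  summaries$relative_rf <- NA_real_
  summaries$relative_rf_prime <- NA_real_
  if (nrow(ref_row) == 1L && !is.na(ref_row$mean_rf) && ref_row$mean_rf > 0) {
    summaries$relative_rf <- vapply(summaries$mean_rf, function(m)
      if (is.na(m)) NA_real_ else relative_rf(m, ref_row$mean_rf),
      numeric(1L))
  }
  if (nrow(ref_row) == 1L && !is.na(ref_row$mean_rf_prime) &&
      ref_row$mean_rf_prime > 0) {
    summaries$relative_rf_prime <- vapply(summaries$mean_rf_prime,
      function(m) if (is.na(m)) NA_real_
                  else relative_rf(m, ref_row$mean_rf_prime), numeric(1L))
  }

  log <- data.frame(
    key = c("n_genes", "n_excluded", "n_excluded_polytomy",
            "n_excluded_overlap", "n_with_pis", "bin_size", "quantile",
            "polytomy_threshold", "reference_set",
            "baseline_a", "baseline_b", "n_points_fit"),
    value = c(nrow(records), sum(records$excluded),
              sum(records$reason %in% "polytomy"),
              sum(records$reason %in% "insufficient_overlap"),
              sum(!is.na(records$n_pis)), config$bin_size, config$quantile,
              config$polytomy_threshold, config$reference_set,
              if (is.null(model)) NA else signif(model$a, 6),
              if (is.null(model)) NA else signif(model$b, 6),
              if (is.null(model)) NA else model$n_points_fit),
    stringsAsFactors = FALSE)

  out <- structure(list(records = records, summaries = summaries,
                        model = model, log = log, config = config),
                   class = "concordance_run")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv6(records, file.path(config$out_dir, "records.tsv"))
    write_tsv6(summaries, file.path(config$out_dir, "summaries.tsv"))
    write_tsv6(log, file.path(config$out_dir, "run_log.tsv"))
    if (!is.null(model))
      write_tsv6(data.frame(a = model$a, b = model$b,
                            bin_size = model$bin_size,
                            quantile = model$quantile,
                            n_points_fit = model$n_points_fit),
                 file.path(config$out_dir, "model.tsv"))
  }
  out
}

#' @export
print.concordance_run <- function(x, ...) {
  cat(sprintf("concordance run: %d gene trees (%d excluded)\n",
              nrow(x$records), sum(x$records$excluded)))
  if (!is.null(x$model)) print(x$model)
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Two-sample t-test on gene-set distances
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom (default), or the pooled-variance Student variant.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @param var_equal use the pooled-variance (classical Student) form?
#' @return a list with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2L, length(y) >= 2L)
  if (sd(x) == 0 && sd(y) == 0)
    stop("both samples have zero variance", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return the sample Pearson correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
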