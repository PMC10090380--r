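# Baseline normalization of RF distances by parsimony-informative-site
# (PIS) content.
#
# Genes with little phylogenetic information yield erratic gene trees and
# inflated RF distances regardless of their true history. The correction
# fits the lower envelope of the RF-versus-PIS cloud -- the "good" gene
# trees at each information level -- as RF = a*log10(N_PIS) + b, and
# divides every RF value by its fitted baseline.

#' Bin RF records by PIS count
#'
#' Records are sorted by ascending `n_pis` (ties broken by `gene_id`,
#' stably) and cut into consecutive equal-sized bins.
#'
#' @param records data.frame with at least `gene_id`, `norm_rf`, `n_pis`;
#'   excluded records and records without a positive PIS count must be
#'   filtered out beforehand.
#' @param bin_size records per bin (default 1000).
#' @param remainder_policy what to do with a trailing chunk smaller than
#'   `bin_size`: `"merge"` (default) folds it into the last full bin when
#'   it is smaller than half a bin and otherwise keeps it as its own bin;
#'   `"keep"` always keeps it separate.
#' @return an ordered list of data.frames. If there are fewer than
#'   `bin_size` records, a single bin holds everything.
#' @export
bin_by_pis <- function(records, bin_size = 1000L,
                       remainder_policy = c("merge", "keep")) {
  remainder_policy <- match.arg(remainder_policy)
  stopifnot(is.data.frame(records),
            all(c("gene_id", "norm_rf", "n_pis") %in% names(records)))
  if (nrow(records) == 0L) stop("no records to bin", call. = FALSE)
  if (any(is.na(records$n_pis)) || any(records$n_pis < 1L))
    stop("all records must have n_pis >= 1", call. = FALSE)
  bin_size <- as.integer(assert_scalar_number(bin_size, "bin_size", 1))

  ord <- order(records$n_pis, records$gene_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  n <- nrow(records)

  if (n <= bin_size) {
    sizes <- n
  } else {
    nb <- n %/% bin_size
    rem <- n - nb * bin_size
    sizes <- rep(bin_size, nb)
    if (rem > 0L) {
      if (remainder_policy == "merge" && rem < bin_size / 2)
        sizes[nb] <- sizes[nb] + rem
      else
        sizes <- c(sizes, rem)
    }
  }
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) records[s:e, , drop = FALSE],
         starts, ends, SIMPLIFY = FALSE)
}

#' Select the lowest RF quantile of a bin
#'
#' Returns the `ceiling(q * n)` records with the smallest `norm_rf`
#' (at least one), ties resolved by the bin's existing (stable) order.
#' These are the "good" gene trees at that information level, the points
#' the baseline is fitted through.
#'
#' @param bin a data.frame, one element of [bin_by_pis()]'s result.
#' @param q lower-tail fraction (default 0.05).
#' @return a data.frame with `ceiling(q * nrow(bin))` rows.
#' @export
select_lower_quantile <- function(bin, q = 0.05) {
  stopifnot(is.data.frame(bin), nrow(bin) >= 1L)
  assert_scalar_number(q, "q", lower = 1e-12, upper = 1)
  k <- max(1L, as.integer(ceiling(q * nrow(bin))))
  idx <- order(bin$norm_rf, method = "radix")[seq_len(k)]
  bin[sort(idx), , drop = FALSE]
}

#' Fit the PIS baseline by ordinary least squares
#'
#' Fits `norm_rf = a * log10(n_pis) + b` through the selected points,
#' unweighted.
#'
#' @param selected data.frame with columns `n_pis` and `norm_rf` (the
#'   pooled per-bin lower-quantile selections).
#' @param bin_size,quantile settings recorded in the model for
#'   provenance.
#' @return an object of class `pis_baseline`: a list with elements `a`
#'   (slope), `b` (intercept), `bin_size`, `quantile`, `n_points_fit`.
#' @export
fit_baseline <- function(selected, bin_size = NA_integer_,
                         quantile = NA_real_) {
  stopifnot(is.data.frame(selected),
            all(c("n_pis", "norm_rf") %in% names(selected)))
  if (nrow(selected) < 2L)
    stop("baseline fit needs at least 2 points", call. = FALSE)
  lx <- log10(selected$n_pis)
  if (length(unique(lx)) < 2L)
    stop("all n_pis identical: baseline slope is unidentifiable",
         call. = FALSE)
  fit <- lm(norm_rf ~ lx, data = data.frame(lx = lx,
                                            norm_rf = selected$norm_rf))
  structure(list(a = unname(coef(fit)[2L]), b = unname(coef(fit)[1L]),
                 bin_size = bin_size, quantile = quantile,
                 n_points_fit = nrow(selected)),
            class = "pis_baseline")
}

#' @export
print.pis_baseline <- function(x, ...) {
  cat(sprintf("PIS baseline: RF = %.4g * log10(N_PIS) + %.4g\n", x$a, x$b))
  cat(sprintf("  fitted through %d points (bin size %s, lower quantile %s)\n",
              x$n_points_fit, x$bin_size, x$quantile))
  invisible(x)
}

#' Fit the PIS baseline from RF records
#'
#' Convenience wrapper running the full bin / select / fit procedure:
#' sort records by PIS count, cut into equal-sized bins, keep the lowest
#' `quantile` of RF values in each bin, and fit the log-linear baseline
#' through the pooled selection.
#'
#' @param records data.frame with `gene_id`, `norm_rf`, `n_pis`,
#'   `excluded` (excluded rows and rows with missing or zero PIS are
#'   dropped with a message).
#' @param bin_size records per bin (default 1000).
#' @param quantile lower-tail fraction kept per bin (default 0.05).
#' @param remainder_policy see [bin_by_pis()].
#' @return a `pis_baseline` model.
#' @export
fit_pis_baseline <- function(records, bin_size = 1000L, quantile = 0.05,
                             remainder_policy = "merge") {
  stopifnot(is.data.frame(records))
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  usable <- !records$excluded & !is.na(records$n_pis) & records$n_pis >= 1L &
    !is.na(records$norm_rf)
  dropped <- nrow(records) - sum(usable)
  if (dropped > 0L)
    message(dropped, " record(s) excluded from the baseline fit")
  bins <- bin_by_pis(records[usable, , drop = FALSE], bin_size,
                     remainder_policy)
  selected <- do.call(rbind, lapply(bins, select_lower_quantile, q = quantile))
  fit_baseline(selected, bin_size = bin_size, quantile = quantile)
}

#' Normalize RF distances by the fitted PIS baseline
#'
#' `RF' = RF / (a * log10(n_pis) + b)`. A value of 1 means a gene tree
#' exactly as discordant as a "good" gene tree with that amount of
#' phylogenetic information; the normalized scale has no upper bound
#' of 1.
#'
#' @param norm_rf numeric vector of normalized RF distances.
#' @param n_pis integer vector of PIS counts (recycled against
#'   `norm_rf`).
#' @param model a `pis_baseline` model.
#' @param epsilon guard threshold: entries whose fitted baseline is not
#'   greater than `epsilon` are returned as `NA` (with a warning) rather
#'   than clamped, so pathological fits stay visible.
#' @return numeric vector of RF' values, `NA` where the baseline is
#'   non-positive.
#' @export
normalize_rf <- function(norm_rf, n_pis, model, epsilon = 1e-6) {
  stopifnot(inherits(model, "pis_baseline"))
  if (any(!is.na(n_pis) & n_pis < 1L))
    stop("n_pis must be >= 1", call. = FALSE)
  baseline <- model$a * log10(as.numeric(n_pis)) + model$b
  bad <- !is.na(baseline) & baseline <= epsilon
  out <- norm_rf / baseline
  if (any(bad)) {
    warning(sum(bad), " record(s) have non-positive fitted baseline; ",
            "RF' set to NA", call. = FALSE)
    out[bad] <- NA_real_
  }
  out
}
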