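# Clade-proportional random genome dataset (RGD) resampling.
#
# To keep orthology inference tractable on hundreds of genomes, the
# design repeatedly draws small genome subsets whose clade composition
# mirrors the full species tree: replicate slots are apportioned across
# clades proportionally to clade size and filled by uniform sampling
# without replacement within each clade.

#' Construct a clade partition
#'
#' @param species_id character vector of species identifiers.
#' @param clade_label parallel vector of clade labels; clade order is the
#'   order of first appearance.
#' @return an object of class `clade_partition`: a named list mapping
#'   clade label to its member species IDs.
#' @export
clade_partition <- function(species_id, clade_label) {
  stopifnot(length(species_id) == length(clade_label),
            length(species_id) >= 1L)
  if (anyDuplicated(species_id))
    stop("species IDs must be unique across clades", call. = FALSE)
  clade_label <- as.character(clade_label)
  parts <- split(as.character(species_id),
                 factor(clade_label, levels = unique(clade_label)))
  if (any(lengths(parts) == 0L)) stop("empty clade", call. = FALSE)
  structure(parts, class = "clade_partition")
}

#' Read a clade partition from a TSV table
#'
#' @param path TSV file with columns `species_id` and `clade_label`.
#' @return a `clade_partition`.
#' @export
read_clade_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", "clade_label")
  if (!all(need %in% names(tab)))
    stop("clade table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  clade_partition(tab$species_id, tab$clade_label)
}

#' Apportion replicate slots across clades (largest remainder)
#'
#' Hamilton / largest-remainder apportionment of `total` slots
#' proportionally to clade sizes: floor the exact quotas, then hand the
#' leftover slots to the clades with the largest fractional remainders
#' (ties broken by clade order). Small clades whose quota rounds to zero
#' receive no slots, so their species are never drawn.
#'
#' @param clade_sizes integer vector of clade sizes.
#' @param total number of slots to allocate (`1 <= total <= sum(sizes)`).
#' @return integer vector of per-clade counts summing to `total`, each
#'   at most the clade size.
#' @examples
#' allocate_clade_counts(c(1, 2, 18, 159, 36, 56, 15, 86), 64)
#' # 0 0 3 27 6 10 3 15
#' @export
allocate_clade_counts <- function(clade_sizes, total) {
  stopifnot(is.numeric(clade_sizes), length(clade_sizes) >= 1L,
            all(clade_sizes >= 1))
  total <- as.integer(assert_scalar_number(total, "total", 1))
  if (total > sum(clade_sizes))
    stop("total exceeds the number of available species", call. = FALSE)
  quota <- total * clade_sizes / sum(clade_sizes)
  counts <- floor(quota)
  left <- total - sum(counts)
  if (left > 0L) {
    # stable order(): ties in remainder fall back to clade order
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  counts <- as.integer(counts)
  if (any(counts > clade_sizes))  # cannot happen for proportional quotas
    stop("allocation exceeds a clade size", call. = FALSE)
  counts
}

#' Draw one random genome dataset
#'
#' Uniform sampling without replacement within each clade, following a
#' per-clade allocation.
#'
#' @param partition a `clade_partition`.
#' @param allocation integer vector, one count per clade (e.g. from
#'   [allocate_clade_counts()]).
#' @param seed optional integer; the draw is deterministic for a given
#'   seed.
#' @return a character vector of distinct species IDs.
#' @export
draw_rgd <- function(partition, allocation, seed = NULL) {
  stopifnot(inherits(partition, "clade_partition"),
            length(allocation) == length(partition))
  if (any(allocation > lengths(partition)))
    stop("allocation exceeds a clade size", call. = FALSE)
  with_seed_if(seed, {
    unlist(mapply(function(members, k) {
      if (k == 0L) character(0) else sample(members, k)
    }, partition, allocation, SIMPLIFY = FALSE), use.names = FALSE)
  })
}

#' Generate a set of random genome datasets
#'
#' Repeats the clade-proportional draw to produce `n_replicates`
#' replicate species sets of equal size. A single master seed spawns one
#' sub-seed per replicate, so the whole set is reproducible.
#'
#' @param partition a `clade_partition`.
#' @param n_replicates number of replicate datasets (default 100).
#' @param size species per replicate (default 64).
#' @param seed master RNG seed (default 1).
#' @return an object of class `rgd_set`: list with `replicates` (list of
#'   species-ID vectors), `size`, `seed`, `allocation`, `n_species_pool`
#'   (total species in the partition).
#' @export
generate_rgds <- function(partition, n_replicates = 100L, size = 64L,
                          seed = 1L) {
  stopifnot(inherits(partition, "clade_partition"))
  n_replicates <- as.integer(assert_scalar_number(n_replicates,
                                                  "n_replicates", 1))
  size <- as.integer(assert_scalar_number(size, "size", 1))
  allocation <- allocate_clade_counts(lengths(partition), size)
  rep_seeds <- with_seed_if(seed,
                            sample.int(2147483646L, n_replicates))
  replicates <- lapply(rep_seeds, function(s)
    draw_rgd(partition, allocation, seed = s))
  structure(list(replicates = replicates, size = size, seed = seed,
                 allocation = allocation,
                 n_species_pool = sum(lengths(partition))),
            class = "rgd_set")
}

#' @export
print.rgd_set <- function(x, ...) {
  cat(sprintf("%d random genome datasets of %d species (seed %s)\n",
              length(x$replicates), x$size, x$seed))
  cat("per-clade allocation:", paste(x$allocation, collapse = " "), "\n")
  invisible(x)
}

#' Resampling diagnostics of an RGD set
#'
#' How often is each species drawn, and how similar are replicates to
#' one another?
#'
#' @param rgds an `rgd_set`.
#' @return a list with `mean_resample` and `sd_resample` (over species
#'   drawn at least once), `mean_resample_all` (over every species in
#'   the source partition, i.e. total draws / pool size),
#'   `max_overlap` (largest pairwise `|intersection| / size` over all
#'   replicate pairs), `n_species_sampled`, and `counts` (named vector
#'   of per-species resampling counts).
#' @export
resampling_stats <- function(rgds) {
  stopifnot(inherits(rgds, "rgd_set"))
  reps <- rgds$replicates
  if (length(reps) < 2L) stop("need at least 2 replicates", call. = FALSE)
  counts <- table(unlist(reps, use.names = FALSE))
  counts <- setNames(as.integer(counts), names(counts))

  species <- names(counts)
  m <- matrix(0L, nrow = length(species), ncol = length(reps),
              dimnames = list(species, NULL))
  for (j in seq_along(reps)) m[reps[[j]], j] <- 1L
  ov <- crossprod(m)
  diag(ov) <- 0L
  list(mean_resample = mean(counts),
       sd_resample = sd(counts),
       mean_resample_all = sum(counts) / rgds$n_species_pool,
       max_overlap = max(ov) / rgds$size,
       n_species_sampled = length(counts),
       counts = counts)
}
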