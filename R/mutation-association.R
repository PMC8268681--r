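mutation_classes <- c("missense", "nonsense", "splice_site", "utr3", "utr5",
                      "synonymous", "other")

#' Mutation class filters
#'
#' Convenience class sets: `coding_mutation_classes` restricts to mutations
#' in coding sequence or splice sites; `utr3_mutation_classes` to 3'UTR
#' mutations (both analyses are run in the mutation-association stage).
#' @export
coding_mutation_classes <- c("missense", "nonsense", "splice_site", "synonymous")

#' @rdname coding_mutation_classes
#' @export
utr3_mutation_classes <- "utr3"

validate_mutations <- function(muts) {
  required <- c("sample_id", "gene_id", "class")
  missing <- setdiff(required, names(muts))
  if (length(missing) > 0) {
    stop("mutation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(muts$class), mutation_classes)
  if (length(bad) > 0) {
    stop("unknown mutation class(es): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(mutation_classes, collapse = ", "),
         call. = FALSE)
  }
  invisible(muts)
}

#' Per-gene, per-group mutation counts
#'
#' Counts mutation records per gene and contrast group; every record counts,
#' so a sample with several mutations in one gene contributes all of them.
#'
#' @param muts Mutation tibble with columns `sample_id`, `gene_id`, `class`
#'   (and optionally `transcript_id`, `chrom`, `pos`).
#' @param samples Sample sheet with `sample_id` and the grouping column.
#' @param class_filter Optional set of mutation classes to keep (e.g.
#'   [coding_mutation_classes]); `NULL` keeps all.
#' @param group_col Grouping column name (default `"group"`).
#' @return Long tibble `gene_id`, `group`, `n` (zero rows are not padded in;
#'   downstream consumers treat absent combinations as 0).
#' @export
mutation_counts <- function(muts, samples, class_filter = NULL,
                            group_col = "group") {
  validate_mutations(muts)
  m <- muts
  if (!is.null(class_filter)) {
    m <- dplyr::filter(m, .data$class %in% class_filter)
  }
  m |>
    dplyr::inner_join(
      dplyr::select(samples, "sample_id", group = dplyr::all_of(group_col)),
      by = "sample_id") |>
    dplyr::count(.data$gene_id, .data$group, name = "n")
}

#' Average per-sample mutation count difference between groups
#'
#' delta(g) = count_B(g) / n_B - count_A(g) / n_A: the difference in average
#' per-sample mutation burden of gene g between the two contrast groups
#' (melanoma minus nevus in the motivating design).
#'
#' @param counts Output of [mutation_counts()].
#' @param samples Sample sheet.
#' @param contrast `c(groupA, groupB)`.
#' @param genes Optional character vector of gene ids to report (padded with
#'   delta 0 when unmutated); defaults to genes present in `counts`.
#' @inheritParams mutation_counts
#' @return Tibble `gene_id`, `delta`.
#' @export
average_count_difference <- function(counts, samples, contrast, genes = NULL,
                                     group_col = "group") {
  cs <- contrast_samples(samples, contrast, group_col)
  wide <- counts |>
    dplyr::filter(.data$group %in% contrast) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0)
  for (g in contrast) if (!g %in% names(wide)) wide[[g]] <- 0
  out <- tibble::tibble(
    gene_id = wide$gene_id,
    delta = wide[[contrast[[2]]]] / length(cs$b) -
      wide[[contrast[[1]]]] / length(cs$a)
  )
  if (!is.null(genes)) {
    out <- tibble::tibble(gene_id = genes) |>
      dplyr::left_join(out, by = "gene_id") |>
      dplyr::mutate(delta = dplyr::coalesce(.data$delta, 0))
  }
  out
}

# Shared length-matched sampler: candidates within a multiplicative window
# around the query length; if fewer than k, top up with nearest remaining
# entries by absolute log-length distance (ties by lexicographic id).
length_matched_ids <- function(query_len, ids, lens, k, window, seed) {
  if (length(ids) < k) {
    stop("pool (", length(ids), ") smaller than background size k = ", k,
         call. = FALSE)
  }
  dist <- abs(log(lens) - log(query_len))
  in_window <- dist <= log(1 + window)
  if (sum(in_window) >= k) {
    cand <- ids[in_window]
    withr::with_seed(seed, sort(sample(cand, k)))
  } else {
    chosen <- ids[in_window]
    rest_ord <- order(dist[!in_window], ids[!in_window])
    topup <- ids[!in_window][rest_ord][seq_len(k - length(chosen))]
    sort(c(chosen, topup))
  }
}

#' Length-matched background genes
#'
#' Selects `k` genes whose median isoform length is within a multiplicative
#' `window` of the query gene's (|log ratio| <= log(1 + window)), sampled
#' uniformly without replacement; when the window holds fewer than `k`
#' candidates the selection is topped up with the nearest genes by
#' log-length distance (ties broken by gene id).
#'
#' @param query Query gene id (excluded from the pool).
#' @param lengths Tibble `gene_id`, `median_length`
#'   ([median_isoform_length()]).
#' @param k Background size (default 100, the cohort analysis' choice).
#' @param window Multiplicative length window (default 0.2, i.e. +/-20%).
#' @param seed Integer seed; the same seed always yields the same selection.
#' @return Character vector of `k` gene ids.
#' @export
length_matched_genes <- function(query, lengths, k = 100, window = 0.2, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(k >= 2)
  pool <- dplyr::filter(lengths, .data$gene_id != query)
  qlen <- lengths$median_length[match(query, lengths$gene_id)]
  if (is.na(qlen)) stop("query gene ", query, " not in length table", call. = FALSE)
  length_matched_ids(qlen, pool$gene_id, pool$median_length, k, window, seed)
}

#' Mutation-count-difference Z-scores against a length-matched background
#'
#' For each query gene (typically the switched genes), compares its average
#' mutation count difference to the empirical distribution of the same
#' statistic over `k` genes of similar median isoform length:
#' z = (delta - bg_mean) / bg_sd. A gene is flagged significant when
#' z > `z_threshold` (one-sided upper tail; 1.6 as used with a 90%
#' confidence band in the motivating analysis). A degenerate background
#' (bg_sd = 0) yields z = Inf when delta exceeds the background mean and 0
#' otherwise, with `degenerate = TRUE`.
#'
#' @param query_genes Character vector of gene ids to score.
#' @param deltas Tibble `gene_id`, `delta` over the whole background pool
#'   ([average_count_difference()] with `genes =` all annotated genes).
#' @param lengths Tibble `gene_id`, `median_length` for the same pool.
#' @param k,window Background size and length window (defaults 100, 0.2).
#' @param z_threshold Significance threshold (default 1.6).
#' @param seed Integer seed; background draws use `seed + i` for the i-th
#'   query so each gene has a reproducible, distinct background.
#' @return Tibble `gene_id`, `delta`, `bg_mean`, `bg_sd`, `z`,
#'   `significant`, `degenerate`.
#' @export
gene_mutation_zscore <- function(query_genes, deltas, lengths, k = 100,
                                 window = 0.2, z_threshold = 1.6, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  delta_of <- stats::setNames(deltas$delta, deltas$gene_id)
  rows <- lapply(seq_along(query_genes), function(i) {
    g <- query_genes[[i]]
    bg <- length_matched_genes(g, lengths, k = k, window = window,
                               seed = seed + i)
    bg_delta <- delta_of[bg]
    if (anyNA(bg_delta)) {
      stop("background gene(s) missing from delta table", call. = FALSE)
    }
    d <- delta_of[[g]]
    mu <- mean(bg_delta)
    sd <- stats::sd(bg_delta)
    degenerate <- sd == 0
    z <- if (degenerate) {
      if (d > mu) Inf else 0
    } else {
      (d - mu) / sd
    }
    tibble::tibble(gene_id = g, delta = d, bg_mean = mu, bg_sd = sd, z = z,
                   significant = z > z_threshold, degenerate = degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Jaccard index of two sample sets
#'
#' |A intersect B| / |A union B|; 0 when the union is empty. Here A is the
#' set of tumor samples carrying a per-sample switch of an isoform and B the
#' set carrying a mutation in the isoform's gene.
#'
#' @param switch_samples,mutated_samples Character vectors of sample ids
#'   (duplicates ignored).
#' @return A number in \[0, 1\].
#' @export
jaccard_index <- function(switch_samples, mutated_samples) {
  a <- unique(switch_samples)
  b <- unique(mutated_samples)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Fraction of tumor samples mutated in a gene
#'
#' @param gene Gene id.
#' @param muts Mutation tibble (see [mutation_counts()]).
#' @param tumor_samples Character vector of the tumor-group sample ids.
#' @param class_filter Optional mutation class filter.
#' @return Fraction in \[0, 1\] of `tumor_samples` with at least one
#'   qualifying mutation in `gene`.
#' @export
mutated_sample_fraction <- function(gene, muts, tumor_samples,
                                    class_filter = NULL) {
  stopifnot(length(tumor_samples) > 0)
  m <- dplyr::filter(muts, .data$gene_id == gene,
                     .data$sample_id %in% tumor_samples)
  if (!is.null(class_filter)) m <- dplyr::filter(m, .data$class %in% class_filter)
  length(unique(m$sample_id)) / length(tumor_samples)
}

#' Jaccard switch-mutation co-occurrence with a length-matched null
#'
#' For every switched isoform, computes the Jaccard index between the tumor
#' samples carrying its per-sample switch and the tumor samples carrying a
#' qualifying mutation in its gene, plus the mutated-sample fraction. Each
#' isoform's index is then standardized against the empirical distribution
#' of the indices of `k` other switched isoforms of similar transcript
#' length (same window/top-up rule as [length_matched_genes()], on
#' transcript length): z = (j - mean_null) / sd_null, significant when
#' z > `z_threshold`.
#'
#' @param switch_calls Per-sample switch calls
#'   ([per_sample_switch_calls()]): `transcript_id`, `gene_id`, `sample_id`,
#'   `switched`.
#' @param muts Mutation tibble.
#' @param tumor_samples Character vector of tumor-group sample ids.
#' @param features Feature tibble ([structural_features()]) supplying
#'   transcript lengths.
#' @param class_filter Optional mutation class filter (run once with
#'   [coding_mutation_classes] and once with [utr3_mutation_classes] to
#'   reproduce the coding and 3'UTR analyses).
#' @param k Null size (default 200, the cohort analysis' choice).
#' @param window Length window (default 0.2).
#' @param z_threshold Significance threshold (default 1.6).
#' @param seed Integer seed; isoform i uses `seed + i`.
#' @return Tibble `transcript_id`, `gene_id`, `j`, `mutated_fraction`,
#'   `bg_mean`, `bg_sd`, `z`, `significant`.
#' @export
jaccard_zscore <- function(switch_calls, muts, tumor_samples, features,
                           class_filter = NULL, k = 200, window = 0.2,
                           z_threshold = 1.6, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  validate_mutations(muts)
  m <- dplyr::filter(muts, .data$sample_id %in% tumor_samples)
  if (!is.null(class_filter)) m <- dplyr::filter(m, .data$class %in% class_filter)
  mut_sets <- split(m$sample_id, m$gene_id)

  iso <- switch_calls |>
    dplyr::distinct(.data$transcript_id, .data$gene_id)
  sw <- dplyr::filter(switch_calls, .data$switched)
  sw_sets <- split(sw$sample_id, sw$transcript_id)

  iso$length <- features$transcript_length[match(iso$transcript_id,
                                                 features$transcript_id)]
  if (anyNA(iso$length)) {
    stop("switched isoform(s) missing from features", call. = FALSE)
  }
  iso$j <- vapply(seq_len(nrow(iso)), function(i) {
    jaccard_index(sw_sets[[iso$transcript_id[i]]] %||% character(0),
                  mut_sets[[iso$gene_id[i]]] %||% character(0))
  }, numeric(1))
  iso$mutated_fraction <- vapply(iso$gene_id, function(g) {
    length(unique(mut_sets[[g]] %||% character(0))) / length(tumor_samples)
  }, numeric(1))

  j_of <- stats::setNames(iso$j, iso$transcript_id)
  zrows <- lapply(seq_len(nrow(iso)), function(i) {
    pool <- iso[-i, ]
    null_ids <- length_matched_ids(iso$length[i], pool$transcript_id,
                                   pool$length, k, window, seed + i)
    null_j <- j_of[null_ids]
    mu <- mean(null_j)
    sd <- stats::sd(null_j)
    z <- if (sd == 0) {
      if (iso$j[i] > mu) Inf else 0
    } else {
      (iso$j[i] - mu) / sd
    }
    tibble::tibble(bg_mean = mu, bg_sd = sd, z = z,
                   significant = z > z_threshold)
  })
  dplyr::bind_cols(dplyr::select(iso, -"length"), dplyr::bind_rows(zrows))
}
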