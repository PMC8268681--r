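#' Read gene sets from a GMT file
#'
#' One tab-separated line per set: set id, description, then member gene
#' ids.
#'
#' @param path Path to a GMT file.
#' @return Tibble `set_id`, `name`, `genes` (list-column of character
#'   vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad) > 0) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    set_id = vapply(parts, `[[`, character(1), 1),
    name = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Hypergeometric gene-set overrepresentation
#'
#' Tests each gene set for overrepresentation in a query gene list against a
#' background universe: with N = |background|, K = |set in background|,
#' n = |query|, k = |overlap|, the enrichment ratio is (k/n)/(K/N) and the
#' p-value the upper-tail hypergeometric probability P(X >= k). FDR by
#' Benjamini-Hochberg across the tested sets.
#'
#' @param query Character vector of query gene ids (must lie in
#'   `background`).
#' @param gene_sets Tibble from [read_gmt()] (`set_id`, `name`, `genes`).
#' @param background Character vector: the gene universe (typically all
#'   genes surviving the expression filter).
#' @return Tibble sorted by p-value: `set_id`, `name`, `n_set`, `n_overlap`,
#'   `enrichment_ratio`, `p_value`, `fdr`, `overlap_genes` (list-column).
#' @export
hypergeom_enrichment <- function(query, gene_sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% background)) {
    stop("query gene(s) outside the background universe: ",
         paste(utils::head(setdiff(query, background), 5), collapse = ", "),
         call. = FALSE)
  }
  n_bg <- length(background)
  n_q <- length(query)
  rows <- purrr::pmap(gene_sets, function(set_id, name, genes, ...) {
    in_bg <- intersect(genes, background)
    overlap <- intersect(genes, query)
    k <- length(overlap)
    K <- length(in_bg)
    ratio <- if (K == 0 || n_q == 0) 0 else (k / n_q) / (K / n_bg)
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, n_bg - K, n_q,
                                          lower.tail = FALSE)
    tibble::tibble(set_id = set_id, name = name, n_set = K, n_overlap = k,
                   enrichment_ratio = ratio, p_value = p,
                   overlap_genes = list(sort(overlap)))
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$set_id) |>
    dplyr::relocate("fdr", .after = "p_value")
}

#' Pairwise overlap between contrasts' switch sets
#'
#' For every pair of contrasts, counts ids exclusive to each and shared by
#' both (the Venn structure used to compare e.g. malignant-transformation
#' and subtype contrasts). Exclusive and shared counts sum to each
#' contrast's set size.
#'
#' @param sets Named list of character vectors (e.g. switched isoform ids or
#'   switched gene ids per contrast). At least two.
#' @return Tibble `contrast_a`, `contrast_b`, `n_a`, `n_b`, `exclusive_a`,
#'   `exclusive_b`, `shared`.
#' @export
contrast_overlap <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  cmb <- utils::combn(names(sets), 2, simplify = FALSE)
  dplyr::bind_rows(lapply(cmb, function(nm) {
    a <- sets[[nm[[1]]]]
    b <- sets[[nm[[2]]]]
    shared <- length(intersect(a, b))
    tibble::tibble(contrast_a = nm[[1]], contrast_b = nm[[2]],
                   n_a = length(a), n_b = length(b),
                   exclusive_a = length(a) - shared,
                   exclusive_b = length(b) - shared,
                   shared = shared)
  }))
}
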