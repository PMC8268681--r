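sample_cols <- function(abund) {
  setdiff(names(abund), c("transcript_id", "gene_id"))
}

abund_matrix <- function(abund, cols = sample_cols(abund)) {
  m <- as.matrix(abund[cols])
  rownames(m) <- abund$transcript_id
  m
}

#' Remove low-expression transcripts
#'
#' Transcripts whose mean abundance across all samples falls below
#' `min_mean_abundance` are dropped, and genes left with no isoform disappear
#' with them. Genes reduced to a single isoform are retained (their overall
#' expression still matters downstream) but can never yield a switch; the
#' usage test marks their isoforms untestable.
#'
#' @param abund Abundance tibble: columns `transcript_id`, `gene_id`, then one
#'   numeric column per sample (TPM or comparable non-negative units).
#' @param min_mean_abundance Mean-abundance threshold (default 1 TPM).
#' @return The filtered abundance tibble.
#' @export
filter_low_expression <- function(abund, min_mean_abundance = 1) {
  stopifnot(min_mean_abundance >= 0)
  m <- abund_matrix(abund)
  if (any(m < 0)) stop("negative abundances are not allowed", call. = FALSE)
  keep <- rowMeans(m) >= min_mean_abundance
  out <- abund[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no transcripts survive filtering", call. = FALSE)
  out
}

#' Per-gene expression totals
#'
#' @param abund Abundance tibble (see [filter_low_expression()]).
#' @return Tibble with `gene_id` and one column per sample holding the summed
#'   abundance of the gene's isoforms.
#' @export
gene_expression <- function(abund) {
  abund |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum), .groups = "drop")
}

#' Isoform fractions (IF)
#'
#' The isoform fraction of transcript i in sample s is its abundance divided
#' by the summed abundance of all isoforms of its gene in that sample. Where
#' a gene's total expression is below `epsilon` the fractions are undefined
#' and set to `NA` (a ratio of noise over noise carries no usage signal).
#'
#' @inheritParams filter_low_expression
#' @param epsilon Minimum gene expression for fractions to be defined
#'   (default 1, same units as the abundances).
#' @return Tibble of the same shape as `abund` with fractions in \[0, 1\] or
#'   `NA` in the sample columns. Per (gene, sample), non-missing fractions
#'   sum to 1.
#' @export
isoform_fractions <- function(abund, epsilon = 1) {
  cols <- sample_cols(abund)
  m <- abund_matrix(abund, cols)
  ge <- rowsum(m, group = abund$gene_id, reorder = FALSE)
  ge_per_tx <- ge[match(abund$gene_id, rownames(ge)), , drop = FALSE]
  frac <- m / ge_per_tx
  frac[ge_per_tx < epsilon] <- NA_real_
  out <- abund
  out[cols] <- tibble::as_tibble(frac)
  out
}

contrast_samples <- function(samples, contrast, group_col = "group") {
  stopifnot(length(contrast) == 2)
  g <- samples[[group_col]]
  if (!all(contrast %in% g)) {
    stop("contrast level(s) absent from sample sheet: ",
         paste(setdiff(contrast, g), collapse = ", "), call. = FALSE)
  }
  list(a = samples$sample_id[g == contrast[[1]]],
       b = samples$sample_id[g == contrast[[2]]])
}

#' Difference in mean isoform fraction between two groups (dIF)
#'
#' dIF is the effect size of differential transcript usage: mean isoform
#' fraction in the second contrast group minus the mean in the first, means
#' taken over samples with defined fractions only.
#'
#' @param fractions Output of [isoform_fractions()].
#' @param samples Sample sheet tibble with columns `sample_id` and the
#'   grouping column.
#' @param contrast Character vector `c(groupA, groupB)`; dIF is B minus A.
#' @param group_col Name of the grouping column in `samples` (default
#'   `"group"`).
#' @return Tibble with `transcript_id`, `gene_id`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b` (usable sample counts), `dIF`, and `testable` (at least two
#'   usable samples per group and a multi-isoform gene).
#' @export
delta_if <- function(fractions, samples, contrast, group_col = "group") {
  cs <- contrast_samples(samples, contrast, group_col)
  ma <- abund_matrix(fractions, cs$a)
  mb <- abund_matrix(fractions, cs$b)
  n_a <- rowSums(!is.na(ma))
  n_b <- rowSums(!is.na(mb))
  mean_a <- rowMeans(ma, na.rm = TRUE)
  mean_b <- rowMeans(mb, na.rm = TRUE)
  n_iso <- table(fractions$gene_id)[fractions$gene_id]
  tibble::tibble(
    transcript_id = fractions$transcript_id,
    gene_id = fractions$gene_id,
    mean_a = ifelse(n_a > 0, mean_a, NA_real_),
    mean_b = ifelse(n_b > 0, mean_b, NA_real_),
    n_a = as.integer(n_a),
    n_b = as.integer(n_b),
    dIF = ifelse(n_a > 0 & n_b > 0, mean_b - mean_a, NA_real_),
    testable = n_a >= 2 & n_b >= 2 & as.integer(n_iso) >= 2
  )
}

#' Permutation test for differential transcript usage
#'
#' Tests each isoform's |dIF| against the null of group-label
#' exchangeability: the group labels are permuted across samples `n_perm`
#' times (each fraction, including its missingness, stays attached to its
#' sample) and the p-value is the add-one estimator
#' (1 + #\{permuted |dIF| >= observed\}) / (n_perm + 1), ties counted as
#' exceedances so p is never 0. Isoforms with fewer than two usable samples
#' in either group under the observed labels are untestable and get `NA`;
#' permutations that leave a group with fewer than two usable samples are
#' excluded from that isoform's count.
#'
#' @inheritParams delta_if
#' @param n_perm Number of label permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream (mandatory:
#'   reproducibility is part of the contract).
#' @return The [delta_if()] tibble with a `p_value` column appended.
#' @export
permutation_test_dtu <- function(fractions, samples, contrast, n_perm = 1000,
                                 seed, group_col = "group") {
  stopifnot(n_perm >= 100)
  if (missing(seed)) stop("a seed is required for the permutation test", call. = FALSE)
  d <- delta_if(fractions, samples, contrast, group_col)
  cs <- contrast_samples(samples, contrast, group_col)
  cols <- c(cs$a, cs$b)
  m <- abund_matrix(fractions, cols)
  is_b <- c(rep(FALSE, length(cs$a)), rep(TRUE, length(cs$b)))
  x0 <- m
  x0[is.na(m)] <- 0
  valid <- (!is.na(m)) * 1

  withr::with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) sample(is_b), logical(length(is_b)))
  })
  pb <- matrix(as.numeric(perm), nrow = length(is_b))
  pa <- 1 - pb
  cnt_b <- valid %*% pb
  cnt_a <- valid %*% pa
  dif_perm <- (x0 %*% pb) / cnt_b - (x0 %*% pa) / cnt_a
  ok <- cnt_a >= 2 & cnt_b >= 2
  dif_perm[!ok] <- NA_real_

  obs <- abs(d$dIF)
  exceed <- rowSums(abs(dif_perm) >= (obs - 1e-12), na.rm = TRUE)
  n_valid <- rowSums(!is.na(dif_perm))
  p <- unname((1 + exceed) / (1 + n_valid))
  p[!d$testable] <- NA_real_
  d$p_value <- p
  d
}

#' Benjamini-Hochberg adjustment with missing-value pass-through
#'
#' Step-up false discovery rate adjustment applied over the non-missing
#' entries only; `NA` p-values (untestable isoforms) stay `NA` and do not
#' count toward the number of tests.
#'
#' @param p Numeric vector of p-values in (0, 1\], possibly with `NA`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Call antagonistic switch pairs
#'
#' Per gene, every (up, down) isoform pair with `dIF_up >= dIF_threshold`,
#' `dIF_down <= -dIF_threshold`, and at least one member significant
#' (`min(q_up, q_down) < q_threshold`) is emitted — the antagonistic-usage
#' definition of an isoform switch: up- or down-regulation of one isoform
#' paralleled by an opposite change in another isoform of the same gene.
#'
#' @param tests Tibble from [permutation_test_dtu()] with a `q_value` column
#'   (see [bh_adjust()]).
#' @param dIF_threshold Minimum absolute dIF for either member (default 0.1).
#' @param q_threshold FDR threshold for the significant member (default
#'   0.05).
#' @return Tibble of switch pairs sorted by `min(q_up, q_down)`:
#'   `gene_id`, `up_isoform`, `down_isoform`, `dIF_up`, `dIF_down`, `p_up`,
#'   `p_down`, `q_up`, `q_down`. May be empty.
#' @export
call_switch_pairs <- function(tests, dIF_threshold = 0.1, q_threshold = 0.05) {
  if (!"q_value" %in% names(tests)) {
    stop("tests must carry a q_value column; see bh_adjust()", call. = FALSE)
  }
  t <- dplyr::filter(tests, !is.na(.data$q_value))
  ups <- dplyr::filter(t, .data$dIF >= dIF_threshold) |>
    dplyr::select("gene_id", up_isoform = "transcript_id",
                  dIF_up = "dIF", p_up = "p_value", q_up = "q_value")
  downs <- dplyr::filter(t, .data$dIF <= -dIF_threshold) |>
    dplyr::select("gene_id", down_isoform = "transcript_id",
                  dIF_down = "dIF", p_down = "p_value", q_down = "q_value")
  pairs <- dplyr::inner_join(ups, downs, by = "gene_id",
                             relationship = "many-to-many") |>
    dplyr::filter(pmin(.data$q_up, .data$q_down) < q_threshold) |>
    dplyr::arrange(pmin(.data$q_up, .data$q_down), .data$gene_id,
                   .data$up_isoform, .data$down_isoform) |>
    dplyr::select("gene_id", "up_isoform", "down_isoform", "dIF_up",
                  "dIF_down", "p_up", "p_down", "q_up", "q_down")
  pairs
}

#' Gene-level switch q-value
#'
#' Aggregates isoform p-values to one value per gene: the minimum member
#' p-value, Bonferroni-scaled by the gene's testable isoform count (capped at
#' 1), then Benjamini-Hochberg adjusted across genes.
#'
#' @param tests Tibble from [permutation_test_dtu()].
#' @return Tibble `gene_id`, `n_testable`, `gene_p`, `gene_q` for genes with
#'   at least one testable isoform.
#' @export
gene_switch_qvalue <- function(tests) {
  g <- tests |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_testable = dplyr::n(),
                     gene_p = pmin(1, min(.data$p_value) * dplyr::n()),
                     .groups = "drop")
  g$gene_q <- bh_adjust(g$gene_p)
  g
}

#' Per-sample switch presence calls
#'
#' For each isoform that is a member of a switch pair, a sample of the second
#' contrast group is called "carrying the switch" when its isoform fraction
#' deviates from the first group's mean fraction in the direction of the
#' group-level dIF by at least `tau_switch`. These calls feed the Jaccard
#' switch-mutation co-occurrence statistic.
#'
#' @inheritParams delta_if
#' @param pairs Switch pairs from [call_switch_pairs()].
#' @param tau_switch Minimum fraction deviation (default 0.1).
#' @return Long tibble `transcript_id`, `gene_id`, `sample_id`, `switched`
#'   over group-B samples; missing fractions are never called.
#' @export
per_sample_switch_calls <- function(fractions, pairs, samples, contrast,
                                    tau_switch = 0.1, group_col = "group") {
  if (nrow(pairs) == 0) stop("no switch pairs to call per-sample switches on", call. = FALSE)
  members <- dplyr::bind_rows(
    tibble::tibble(gene_id = pairs$gene_id, transcript_id = pairs$up_isoform,
                   direction = 1),
    tibble::tibble(gene_id = pairs$gene_id, transcript_id = pairs$down_isoform,
                   direction = -1)
  ) |> dplyr::distinct()
  cs <- contrast_samples(samples, contrast, group_col)
  fr <- fractions[match(members$transcript_id, fractions$transcript_id), ]
  mean_a <- rowMeans(abund_matrix(fr, cs$a), na.rm = TRUE)
  fb <- abund_matrix(fr, cs$b)
  dev <- fb - mean_a
  called <- !is.na(dev) & sign(dev) == members$direction & abs(dev) >= tau_switch
  tibble::tibble(
    transcript_id = rep(members$transcript_id, times = length(cs$b)),
    gene_id = rep(members$gene_id, times = length(cs$b)),
    sample_id = rep(cs$b, each = nrow(members)),
    switched = as.vector(called)
  )
}

#' Detect antagonistic isoform switches between two groups
#'
#' End-to-end switch detection: expression filter, isoform fractions,
#' permutation test for differential usage, FDR adjustment, antagonistic
#' pair calling, gene-level q-values, and per-sample switch calls.
#'
#' @inheritParams permutation_test_dtu
#' @param abund Abundance tibble: `transcript_id`, `gene_id`, one numeric
#'   column per sample.
#' @param min_mean_abundance Expression filter threshold (default 1 TPM).
#' @param epsilon Minimum gene expression for defined fractions (default 1).
#' @param dIF_threshold,q_threshold Switch-pair thresholds (defaults 0.1 and
#'   0.05).
#' @param tau_switch Per-sample switch-call threshold (default 0.1).
#' @return An object of class `switch_fit` with elements `tests` (per-isoform
#'   dIF, p, q), `pairs` (switch pairs with `gene_q` attached), `gene_q`,
#'   `switch_calls`, `fractions`, `samples`, `contrast` and `params`.
#'   [tidy()] returns the pair table, [glance()] a one-row summary,
#'   [autoplot()] a dIF-versus-significance volcano.
#' @export
detect_switches <- function(abund, samples, contrast, group_col = "group",
                            min_mean_abundance = 1, epsilon = 1,
                            n_perm = 1000, dIF_threshold = 0.1,
                            q_threshold = 0.05, tau_switch = 0.1, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  filtered <- filter_low_expression(abund, min_mean_abundance)
  fractions <- isoform_fractions(filtered, epsilon)
  tests <- permutation_test_dtu(fractions, samples, contrast,
                                n_perm = n_perm, seed = seed,
                                group_col = group_col)
  tests$q_value <- bh_adjust(tests$p_value)
  pairs <- call_switch_pairs(tests, dIF_threshold, q_threshold)
  gene_q <- gene_switch_qvalue(tests)
  pairs <- dplyr::left_join(pairs,
                            dplyr::select(gene_q, "gene_id", "gene_q"),
                            by = "gene_id")
  calls <- if (nrow(pairs) > 0) {
    per_sample_switch_calls(fractions, pairs, samples, contrast,
                            tau_switch, group_col)
  } else {
    tibble::tibble(transcript_id = character(), gene_id = character(),
                   sample_id = character(), switched = logical())
  }
  structure(
    list(tests = tests, pairs = pairs, gene_q = gene_q,
         switch_calls = calls, fractions = fractions, samples = samples,
         contrast = contrast,
         params = list(group_col = group_col,
                       min_mean_abundance = min_mean_abundance,
                       epsilon = epsilon, n_perm = n_perm,
                       dIF_threshold = dIF_threshold,
                       q_threshold = q_threshold, tau_switch = tau_switch,
                       seed = seed)),
    class = "switch_fit"
  )
}

#' @export
print.switch_fit <- function(x, ...) {
  cat("Isoform switch fit:", x$contrast[[1]], "vs", x$contrast[[2]], "\n")
  cat("  ", sum(!is.na(x$tests$p_value)), "testable isoforms in",
      dplyr::n_distinct(x$tests$gene_id), "genes\n")
  cat("  ", nrow(x$pairs), "switch pairs in",
      dplyr::n_distinct(x$pairs$gene_id), "genes\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.switch_fit <- function(x, ...) {
  x$pairs
}

#' @exportS3Method generics::glance
glance.switch_fit <- function(x, ...) {
  tibble::tibble(
    n_isoforms = nrow(x$tests),
    n_testable = sum(!is.na(x$tests$p_value)),
    n_genes = dplyr::n_distinct(x$tests$gene_id),
    n_switch_pairs = nrow(x$pairs),
    n_switch_genes = dplyr::n_distinct(x$pairs$gene_id),
    n_switch_isoforms = dplyr::n_distinct(c(x$pairs$up_isoform,
                                            x$pairs$down_isoform))
  )
}

#' All isoforms that appear in some switch pair
#'
#' @param pairs Switch-pair tibble.
#' @return Tibble `transcript_id`, `gene_id`, `dIF` (the member's usage
#'   change), deduplicated.
#' @export
switched_isoforms <- function(pairs) {
  dplyr::bind_rows(
    dplyr::select(pairs, "gene_id", transcript_id = "up_isoform", dIF = "dIF_up"),
    dplyr::select(pairs, "gene_id", transcript_id = "down_isoform", dIF = "dIF_down")
  ) |> dplyr::distinct(.data$transcript_id, .keep_all = TRUE)
}
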