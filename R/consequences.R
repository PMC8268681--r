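consequence_vocabulary <- c(
  "ORF_loss", "ORF_gain", "domain_loss", "domain_gain",
  "intron_loss", "intron_gain", "utr3_shortened", "utr3_lengthened",
  "utr5_shortened", "utr5_lengthened", "length_shortened", "length_lengthened"
)

# Opposing label for each category; used by the mirror-image property and the
# asymmetry summary.
opposite_label <- function(x) {
  swap <- c(ORF_loss = "ORF_gain", ORF_gain = "ORF_loss",
            domain_loss = "domain_gain", domain_gain = "domain_loss",
            intron_loss = "intron_gain", intron_gain = "intron_loss",
            utr3_shortened = "utr3_lengthened", utr3_lengthened = "utr3_shortened",
            utr5_shortened = "utr5_lengthened", utr5_lengthened = "utr5_shortened",
            length_shortened = "length_lengthened",
            length_lengthened = "length_shortened")
  unname(swap[x])
}

classify_one <- function(up, down, utr_min_diff, len_min_diff) {
  out <- character(0)
  if (down$coding && !up$coding) out <- c(out, "ORF_loss")
  if (!down$coding && up$coding) out <- c(out, "ORF_gain")
  dom_up <- up$domains[[1]]
  dom_down <- down$domains[[1]]
  if (length(setdiff(dom_up, dom_down)) > 0) out <- c(out, "domain_gain")
  if (length(setdiff(dom_down, dom_up)) > 0) out <- c(out, "domain_loss")
  if (up$intron_count < down$intron_count) out <- c(out, "intron_loss")
  if (up$intron_count > down$intron_count) out <- c(out, "intron_gain")
  # UTR comparisons only make sense between two coding isoforms: non-coding
  # transcripts carry UTR length 0 by convention, and their difference is an
  # artifact of that convention, not a UTR change (ORF_loss/gain covers it).
  if (up$coding && down$coding) {
    if (down$utr3_length - up$utr3_length >= utr_min_diff) out <- c(out, "utr3_shortened")
    if (up$utr3_length - down$utr3_length >= utr_min_diff) out <- c(out, "utr3_lengthened")
    if (down$utr5_length - up$utr5_length >= utr_min_diff) out <- c(out, "utr5_shortened")
    if (up$utr5_length - down$utr5_length >= utr_min_diff) out <- c(out, "utr5_lengthened")
  }
  if (down$transcript_length - up$transcript_length >= len_min_diff) {
    out <- c(out, "length_shortened")
  }
  if (up$transcript_length - down$transcript_length >= len_min_diff) {
    out <- c(out, "length_lengthened")
  }
  out
}

#' Classify the functional consequences of switch pairs
#'
#' For every switch pair, compares the up-regulated isoform's structural
#' features against the down-regulated one's and labels the differences from
#' the up-isoform's perspective: `ORF_loss`/`ORF_gain` (coding status),
#' `domain_loss`/`domain_gain` (set differences of annotated domains; both
#' can co-occur), `intron_loss`/`intron_gain`, `utr3_*`/`utr5_*`
#' shortening/lengthening (coding pairs only, difference at least
#' `utr_min_diff`) and spliced `length_*` change (difference at least
#' `len_min_diff`).
#'
#' @param pairs Switch pairs ([call_switch_pairs()]), or any tibble with
#'   `gene_id`, `up_isoform`, `down_isoform`.
#' @param features Feature tibble from [structural_features()].
#' @param utr_min_diff Minimum UTR length difference in nt (default 50, a
#'   small buffer against annotation jitter).
#' @param len_min_diff Minimum transcript length difference in nt (default
#'   50).
#' @return Tibble `gene_id`, `up_isoform`, `down_isoform`, `consequences`
#'   (list-column of label vectors, possibly empty).
#' @export
classify_switch_consequences <- function(pairs, features, utr_min_diff = 50,
                                         len_min_diff = 50) {
  idx <- function(id) {
    i <- match(id, features$transcript_id)
    if (anyNA(i)) {
      stop("switch pair isoform(s) missing from features: ",
           paste(id[is.na(i)], collapse = ", "), call. = FALSE)
    }
    i
  }
  iu <- idx(pairs$up_isoform)
  id <- idx(pairs$down_isoform)
  cons <- lapply(seq_len(nrow(pairs)), function(k) {
    classify_one(features[iu[k], ], features[id[k], ], utr_min_diff, len_min_diff)
  })
  tibble::tibble(
    gene_id = pairs$gene_id,
    up_isoform = pairs$up_isoform,
    down_isoform = pairs$down_isoform,
    consequences = cons
  )
}

#' Summarize genome-wide consequence asymmetries
#'
#' For each opposing consequence pair (e.g. 3'UTR shortened vs lengthened),
#' counts genes by their majority direction over that gene's switch pairs
#' (genes whose pairs tie are dropped) and tests the direction asymmetry
#' with a two-sided exact binomial test against a null proportion of 0.5.
#'
#' @param records Output of [classify_switch_consequences()].
#' @return Tibble with one row per consequence category: `category`,
#'   `opposite`, `genes_affected` (majority-direction gene count for the
#'   category), `genes_opposite`, `genes_tied`, `fraction_of_genes`
#'   (`genes_affected` over all genes with any call in the pair, ties
#'   included), and `asymmetry_p`
#'   (shared within an opposing pair). Empty input yields zero counts and
#'   p = 1.
#' @export
summarize_consequences <- function(records) {
  long <- if (nrow(records) == 0) {
    tibble::tibble(gene_id = character(), label = character())
  } else {
    tidyr::unnest(dplyr::select(records, "gene_id", label = "consequences"),
                  cols = "label")
  }
  halves <- consequence_vocabulary[seq(1, length(consequence_vocabulary), by = 2)]
  rows <- lapply(halves, function(cat) {
    opp <- opposite_label(cat)
    counts <- long |>
      dplyr::filter(.data$label %in% c(cat, opp)) |>
      dplyr::count(.data$gene_id, .data$label) |>
      tidyr::pivot_wider(names_from = "label", values_from = "n",
                         values_fill = 0)
    for (col in c(cat, opp)) if (!col %in% names(counts)) counts[[col]] <- 0
    n1 <- sum(counts[[cat]] > counts[[opp]])
    n2 <- sum(counts[[opp]] > counts[[cat]])
    ties <- nrow(counts) - n1 - n2
    p <- if (n1 + n2 == 0) 1 else stats::binom.test(n1, n1 + n2, 0.5)$p.value
    tibble::tibble(
      category = c(cat, opp), opposite = c(opp, cat),
      genes_affected = c(n1, n2), genes_opposite = c(n2, n1),
      genes_tied = ties,
      fraction_of_genes = if (n1 + n2 + ties == 0) c(0, 0) else
        c(n1, n2) / (n1 + n2 + ties),
      asymmetry_p = p
    )
  })
  dplyr::bind_rows(rows)
}
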