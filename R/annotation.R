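#' Validate a transcript model table
#'
#' Transcript models are held in a long tibble with one row per exon or CDS
#' interval. Coordinates are 0-based, half-open (converted from GTF's 1-based
#' closed convention at parse time by [read_gtf()]).
#'
#' @param models A tibble with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `strand` (`"+"` or `"-"`), `feature` (`"exon"` or `"CDS"`),
#'   `start`, `end`.
#' @return `models`, invisibly, after checking the structural invariants:
#'   every transcript has at least one exon, exons are pairwise disjoint, and
#'   every CDS base lies inside an exon of the same transcript.
#' @export
validate_models <- function(models) {
  required <- c("transcript_id", "gene_id", "strand", "feature", "start", "end")
  missing <- setdiff(required, names(models))
  if (length(missing) > 0) {
    stop("transcript model table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(models$feature %in% c("exon", "CDS"))) {
    stop("feature column must be 'exon' or 'CDS'", call. = FALSE)
  }
  if (any(models$end <= models$start)) {
    stop("empty or inverted interval(s) in transcript models", call. = FALSE)
  }
  if (!all(models$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  by_tx <- split(models, models$transcript_id)
  for (tx in by_tx) {
    id <- tx$transcript_id[[1]]
    ex <- dplyr::arrange(dplyr::filter(tx, .data$feature == "exon"), .data$start)
    if (nrow(ex) == 0) {
      stop("transcript ", id, " has no exons", call. = FALSE)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("transcript ", id, " has overlapping exons", call. = FALSE)
    }
    cds <- dplyr::filter(tx, .data$feature == "CDS")
    if (nrow(cds) > 0) {
      inside <- vapply(seq_len(nrow(cds)), function(i) {
        any(cds$start[i] >= ex$start & cds$end[i] <= ex$end)
      }, logical(1))
      if (!all(inside)) {
        stop("malformed CDS outside exons for transcript ", id, call. = FALSE)
      }
    }
  }
  invisible(models)
}

# Map a genomic position (0-based) to spliced transcript coordinates along the
# genomic (+) direction. `exons` must be sorted by start.
spliced_pos <- function(pos, exon_start, exon_end) {
  cum <- cumsum(c(0, (exon_end - exon_start)[-length(exon_start)]))
  i <- which(pos >= exon_start & pos <= exon_end)[1]
  cum[i] + (pos - exon_start[i])
}

features_one <- function(tx) {
  ex <- dplyr::arrange(dplyr::filter(tx, .data$feature == "exon"), .data$start)
  cds <- dplyr::filter(tx, .data$feature == "CDS")
  strand <- tx$strand[[1]]
  len <- sum(ex$end - ex$start)
  coding <- nrow(cds) > 0
  utr5 <- 0
  utr3 <- 0
  if (coding) {
    sp_start <- min(vapply(cds$start, spliced_pos, numeric(1),
                           exon_start = ex$start, exon_end = ex$end))
    sp_end <- max(vapply(cds$end, spliced_pos, numeric(1),
                         exon_start = ex$start, exon_end = ex$end))
    if (strand == "+") {
      utr5 <- sp_start
      utr3 <- len - sp_end
    } else {
      utr5 <- len - sp_end
      utr3 <- sp_start
    }
  }
  tibble::tibble(
    transcript_id = tx$transcript_id[[1]],
    gene_id = tx$gene_id[[1]],
    strand = strand,
    coding = coding,
    transcript_length = len,
    utr5_length = utr5,
    utr3_length = utr3,
    intron_count = nrow(ex) - 1L
  )
}

#' Derive structural features for every transcript
#'
#' Computes, in spliced (transcript) coordinates, the feature vector used by
#' the consequence classifier: total length, 5'/3' untranslated region
#' lengths, intron count, coding status, and protein domain annotations.
#' The 5'/3' orientation respects strand: on the "-" strand the 3'UTR is the
#' upstream end in genomic coordinates.
#'
#' Non-coding transcripts get UTR lengths of 0 by convention and an empty
#' domain set; the absence of an open reading frame is carried by the
#' `coding` flag instead.
#'
#' @param models Transcript model tibble (see [validate_models()]).
#' @param domains Optional domain annotation tibble with columns
#'   `transcript_id`, `domain_name`, `start_aa`, `end_aa` (e.g. precomputed
#'   Pfam assignments). Domains for non-coding transcripts are dropped.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `strand`, `coding`, `transcript_length`, `utr5_length`, `utr3_length`,
#'   `intron_count`, and a `domains` list-column of character vectors.
#' @examples
#' models <- tibble::tibble(
#'   transcript_id = "tx1", gene_id = "g1", gene_name = "G1", strand = "+",
#'   feature = c("exon", "exon", "CDS", "CDS"),
#'   start = c(0L, 200L, 10L, 200L), end = c(100L, 300L, 100L, 250L)
#' )
#' structural_features(models)
#' @export
structural_features <- function(models, domains = NULL) {
  validate_models(models)
  out <- dplyr::bind_rows(lapply(split(models, models$transcript_id), features_one))
  out <- dplyr::arrange(out, .data$gene_id, .data$transcript_id)
  if (is.null(domains) || nrow(domains) == 0) {
    out$domains <- rep(list(character(0)), nrow(out))
  } else {
    dom <- split(as.character(domains$domain_name),
                 as.character(domains$transcript_id))
    out$domains <- lapply(seq_len(nrow(out)), function(i) {
      if (!out$coding[i]) return(character(0))
      sort(unique(dom[[out$transcript_id[i]]] %||% character(0)))
    })
  }
  out
}

#' Median isoform length per gene
#'
#' The median of the spliced lengths of a gene's transcripts, used to build
#' length-matched backgrounds for the mutation statistics (mutation burden
#' scales with gene length, so the null must be length-controlled).
#'
#' @param features Output of [structural_features()].
#' @return Tibble with columns `gene_id`, `median_length`. Even transcript
#'   counts use the mean of the two central lengths.
#' @export
median_isoform_length <- function(features) {
  if (nrow(features) == 0) stop("no transcripts: cannot take median length", call. = FALSE)
  features |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(median_length = stats::median(.data$transcript_length),
                     .groups = "drop")
}
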