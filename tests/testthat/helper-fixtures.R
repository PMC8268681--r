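# Small hand-built fixtures shared across tests.

# One gene, two exons, CDS spanning spliced positions [10, 150) on "+".
two_exon_model <- function(strand = "+") {
  tibble::tibble(
    transcript_id = "tx1", gene_id = "g1", gene_name = "G1",
    chrom = "chr1", strand = strand,
    feature = c("exon", "exon", "CDS", "CDS"),
    start = c(0L, 200L, 10L, 200L),
    end = c(100L, 300L, 100L, 250L)
  )
}

# Reflect all coordinates of a model table through `span` and flip strand;
# used by the strand-symmetry property.
reflect_model <- function(models, span) {
  out <- models
  out$start <- span - models$end
  out$end <- span - models$start
  out$strand <- ifelse(models$strand == "+", "-", "+")
  out
}

# Abundance tibble for toy cases: `mat` is transcripts x samples.
toy_abundance <- function(mat, gene_ids, sample_ids = paste0("s", seq_len(ncol(mat)))) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  dplyr::bind_cols(
    tibble::tibble(transcript_id = rownames(mat), gene_id = gene_ids),
    tibble::as_tibble(stats::setNames(as.data.frame(mat), sample_ids))
  )
}

toy_samples <- function(n_a, n_b, groups = c("nevus", "melanoma")) {
  tibble::tibble(
    sample_id = c(paste0("a", seq_len(n_a)), paste0("b", seq_len(n_b))),
    group = c(rep(groups[1], n_a), rep(groups[2], n_b))
  )
}

# Feature-vector row in the structural_features() shape.
toy_features <- function(transcript_id, coding = TRUE, length = 1000,
                         utr5 = 100, utr3 = 300, introns = 2,
                         domains = character(0), gene_id = "g1") {
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, strand = "+",
    coding = coding, transcript_length = length,
    utr5_length = if (coding) utr5 else 0,
    utr3_length = if (coding) utr3 else 0,
    intron_count = introns,
    domains = list(if (coding) domains else character(0))
  )
}

# Two-group null fractions: one gene with two isoforms, exchangeable labels.
null_fraction_matrix <- function(n_iso_genes, n_a, n_b, concentration = 20,
                                 seed = 99) {
  withr::with_seed(seed, {
    n_s <- n_a + n_b
    rows <- lapply(seq_len(n_iso_genes), function(g) {
      p <- stats::rbeta(1, 2, 2)
      f1 <- stats::rbeta(n_s, concentration * p, concentration * (1 - p))
      m <- rbind(f1, 1 - f1)
      rownames(m) <- sprintf("g%d.t%d", g, 1:2)
      toy_abundance(m, gene_ids = rep(sprintf("g%d", g), 2),
                    sample_ids = c(paste0("a", seq_len(n_a)),
                                   paste0("b", seq_len(n_b))))
    })
    dplyr::bind_rows(rows)
  })
}
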