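#' Read transcript models from a GTF file
#'
#' Imports exon and CDS features, requiring `gene_id` and `transcript_id`
#' attributes, and converts GTF's 1-based closed coordinates to the 0-based
#' half-open convention used internally.
#'
#' @param path Path to a GTF file.
#' @return Transcript model tibble (`transcript_id`, `gene_id`, `gene_name`,
#'   `chrom`, `strand`, `feature`, `start`, `end`), validated with
#'   [validate_models()]. An empty file yields an empty tibble with a
#'   warning.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(transcript_id = character(), gene_id = character(),
                          gene_name = character(), chrom = character(),
                          strand = character(), feature = character(),
                          start = integer(), end = integer())
  content <- readLines(path, warn = FALSE)
  if (!any(nzchar(content) & !startsWith(content, "#"))) {
    warning("empty GTF file: ", path, call. = FALSE)
    return(empty)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gtf() needs the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  for (col in c("gene_id", "transcript_id")) {
    if (is.null(df[[col]]) || anyNA(df[[col]])) {
      bad <- if (is.null(df[[col]])) seq_len(nrow(df)) else which(is.na(df[[col]]))
      stop("GTF record(s) without ", col, " attribute (record ",
           paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    transcript_id = as.character(df$transcript_id),
    gene_id = as.character(df$gene_id),
    gene_name = if (is.null(df$gene_name)) as.character(df$gene_id)
      else as.character(df$gene_name),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    feature = as.character(df$type),
    start = as.integer(df$start) - 1L,  # 1-based closed -> 0-based half-open
    end = as.integer(df$end)
  )
  validate_models(out)
  out
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates become
#' GTF's 1-based closed ones. Output is deterministic for a given table.
#'
#' @param models Transcript model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  validate_models(models)
  m <- dplyr::arrange(models, .data$gene_id, .data$transcript_id,
                      .data$feature, .data$start)
  gene_name <- if ("gene_name" %in% names(m)) m$gene_name else m$gene_id
  chrom <- if ("chrom" %in% names(m)) m$chrom else "chr1"
  lines <- sprintf(
    '%s\tswitchscape\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
    chrom, m$feature, m$start + 1L, m$end, m$strand,
    m$gene_id, m$transcript_id, gene_name
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `group` and optionally
#'   `subtype`.
#' @return Tibble.
#' @export
read_samples <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(c("sample_id", "group"), names(s))
  if (length(missing) > 0) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id in sheet", call. = FALSE)
  s
}

#' Read a transcript abundance matrix
#'
#' @param path TSV whose first column is `transcript_id` and remaining
#'   header names are sample ids.
#' @param samples Sample sheet ([read_samples()]); every matrix sample must
#'   appear in it. Sheet samples absent from the matrix are dropped with a
#'   warning.
#' @param tx2gene Tibble `transcript_id`, `gene_id` (e.g. from [read_gtf()]
#'   output); every matrix transcript must map to a gene.
#' @return List with `abundance` (tibble `transcript_id`, `gene_id`, sample
#'   columns) and `samples` (the sheet restricted to matrix samples).
#' @export
read_expression <- function(path, samples, tx2gene) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (names(x)[[1]] != "transcript_id") {
    stop("expression matrix must have transcript_id as first column", call. = FALSE)
  }
  cols <- setdiff(names(x), "transcript_id")
  not_num <- cols[!vapply(x[cols], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric abundance column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(cols, samples$sample_id)
  if (length(unknown) > 0) {
    stop("matrix sample(s) missing from sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(samples$sample_id, cols)
  if (length(extra) > 0) {
    warning("sample sheet entries absent from matrix are dropped: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x[cols])
  if (any(m < 0, na.rm = TRUE)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at transcript ", x$transcript_id[idx[1]],
         ", sample ", cols[idx[2]], call. = FALSE)
  }
  t2g <- dplyr::distinct(tx2gene[c("transcript_id", "gene_id")])
  gene <- t2g$gene_id[match(x$transcript_id, t2g$transcript_id)]
  if (anyNA(gene)) {
    stop("transcript(s) without gene mapping: ",
         paste(utils::head(x$transcript_id[is.na(gene)], 5), collapse = ", "),
         call. = FALSE)
  }
  abund <- dplyr::bind_cols(
    tibble::tibble(transcript_id = x$transcript_id, gene_id = gene),
    x[cols]
  )
  list(abundance = abund,
       samples = samples[samples$sample_id %in% cols, , drop = FALSE])
}

#' Read a mutation table
#'
#' @param path MAF-like TSV with columns `sample_id`, `gene_id`, `class` and
#'   optionally `transcript_id`, `chrom`, `pos` (1-based, converted to the
#'   internal 0-based convention).
#' @return Mutation tibble with validated class vocabulary.
#' @export
read_mutations <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                       col_types = readr::cols(.default = readr::col_guess(),
                                               class = readr::col_character()))
  validate_mutations(m)
  if ("pos" %in% names(m)) m$pos <- as.integer(m$pos) - 1L
  m
}

#' Read a domain annotation side table
#'
#' @param path TSV with columns `transcript_id`, `domain_name`, `start_aa`,
#'   `end_aa`.
#' @return Tibble.
#' @export
read_domains <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(c("transcript_id", "domain_name", "start_aa", "end_aa"),
                     names(d))
  if (length(missing) > 0) {
    stop("domain table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Tibble `set_id`, `name`, `genes` (list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$set_id[[i]], gene_sets$name[[i]],
            gene_sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the formats the readers consume: `annotation.gtf`, `domains.tsv`,
#' `expression.tsv`, `samples.tsv`, `mutations.tsv` (positions written
#' 1-based), `gene_sets.gmt`, and ground-truth tables
#' (`truth_switch_pairs.tsv`, `truth_switch_calls.tsv`,
#' `truth_mut_enriched.tsv`, `truth_cooccur.tsv`). All outputs round-trip
#' losslessly through the package readers.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(sim$models, p("annotation.gtf"))
  readr::write_tsv(sim$domains, p("domains.tsv"))
  expr_out <- dplyr::select(sim$abundance, -"gene_id")
  readr::write_tsv(expr_out, p("expression.tsv"))
  readr::write_tsv(sim$samples, p("samples.tsv"))
  mut_out <- sim$mutations
  if ("pos" %in% names(mut_out)) mut_out$pos <- mut_out$pos + 1L
  readr::write_tsv(mut_out, p("mutations.tsv"))
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  readr::write_tsv(sim$truth$pairs, p("truth_switch_pairs.tsv"))
  readr::write_tsv(sim$truth$switch_calls, p("truth_switch_calls.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = sim$truth$mut_enriched_genes),
                   p("truth_mut_enriched.tsv"))
  readr::write_tsv(tibble::tibble(transcript_id = sim$truth$cooccur_isoforms),
                   p("truth_cooccur.tsv"))
  invisible(c(
    gtf = p("annotation.gtf"), domains = p("domains.tsv"),
    expression = p("expression.tsv"), samples = p("samples.tsv"),
    mutations = p("mutations.tsv"), gene_sets = p("gene_sets.gmt")
  ))
}
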