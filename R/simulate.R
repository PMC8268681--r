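#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the motivating study design: 23 benign nevi vs 57
#' primary melanomas, ~500 genes carrying 1-5 transcript isoforms, a
#' minority of genes with planted antagonistic usage switches, gene-length
#' dependent mutation burdens, a subset of mutation-enriched genes, and a
#' subset of switched isoforms with planted switch-mutation co-occurrence.
#'
#' @param seed Master seed; the annotation, expression, mutation and
#'   gene-set generators use `seed`, `seed + 1`, `seed + 2`, `seed + 3`.
#' @param n_genes Number of genes (default 500).
#' @param max_isoforms Maximum isoforms per gene (default 5; minimum 1).
#' @param n_nevus,n_melanoma Group sizes (defaults 23 and 57).
#' @param n_switch_genes Genes with a planted antagonistic switch (default
#'   50).
#' @param dIF_effect Usage mass moved from the down- to the up-isoform in
#'   the melanoma group (default 0.3; must be < 0.55 so proportions stay
#'   valid).
#' @param usage_concentration Dirichlet concentration of per-sample usage
#'   around the group proportions (default 30: within-group isoform-fraction
#'   standard deviations around 0.07-0.09, in line with bulk cohorts).
#' @param gene_mean_log,gene_mean_log_sd Log-normal parameters of gene mean
#'   expression (defaults log(50) and 1).
#' @param nb_dispersion Negative-binomial dispersion of per-sample gene
#'   totals (default 0.3).
#' @param base_mut_rate_per_kb Poisson mutation rate per kb of median
#'   isoform length, per sample (default 0.2).
#' @param n_mut_enriched_genes Genes whose melanoma mutation rate is
#'   multiplied by `mut_fold` (default 20).
#' @param mut_fold Melanoma mutation-rate fold change for enriched genes
#'   (default 3).
#' @param n_cooccur_isoforms Switched up-isoforms with planted
#'   switch-mutation co-occurrence (default 20).
#' @param cooccur_rho Probability that a melanoma sample carrying the
#'   per-sample switch of a co-occurrence isoform is mutated in its gene
#'   (default 0.8).
#' @param frac_utr3_shortened Fraction of coding switch pairs planted with a
#'   shortened 3'UTR on the up-isoform (default 0.6); planted as an exact
#'   count so the planted asymmetry is not itself a random variable.
#' @param frac_orf_loss Fraction of switch pairs planted with a non-coding
#'   up-isoform (default 0.1).
#' @param tau_switch Per-sample switch threshold used for the ground-truth
#'   switch calls (default 0.1, matching the detection default).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 500, max_isoforms = 5,
                       n_nevus = 23, n_melanoma = 57, n_switch_genes = 50,
                       dIF_effect = 0.3, usage_concentration = 30,
                       gene_mean_log = log(50), gene_mean_log_sd = 1,
                       nb_dispersion = 0.3, base_mut_rate_per_kb = 0.2,
                       n_mut_enriched_genes = 20, mut_fold = 3,
                       n_cooccur_isoforms = 20, cooccur_rho = 0.8,
                       frac_utr3_shortened = 0.6, frac_orf_loss = 0.1,
                       tau_switch = 0.1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_genes >= 1, cfg$max_isoforms >= 1, cfg$max_isoforms <= 5,
    cfg$n_nevus >= 1, cfg$n_melanoma >= 1,
    cfg$n_switch_genes >= 0, cfg$n_switch_genes <= cfg$n_genes,
    cfg$dIF_effect >= 0, cfg$dIF_effect < 0.55,
    cfg$usage_concentration > 0, cfg$nb_dispersion > 0,
    cfg$base_mut_rate_per_kb >= 0, cfg$mut_fold >= 1,
    cfg$cooccur_rho >= 0, cfg$cooccur_rho <= 1,
    cfg$frac_utr3_shortened >= 0, cfg$frac_utr3_shortened <= 1,
    cfg$frac_orf_loss >= 0, cfg$frac_orf_loss <= 1
  )
  structure(cfg, class = "sim_config")
}

# Split a spliced length into n_exons exon lengths (each >= 50 nt when
# possible) and lay them on the genome from `gene_start` with random introns.
# Returns exon start/end vectors (0-based half-open, sorted).
lay_exons <- function(total_len, n_exons, gene_start) {
  n_exons <- max(1L, min(n_exons, total_len %/% 60))
  if (n_exons == 1) {
    widths <- total_len
  } else {
    cuts <- sort(sample(seq(50, total_len - 50), n_exons - 1))
    # enforce a minimal exon width by spreading degenerate cuts
    widths <- diff(c(0, cuts, total_len))
    while (any(widths < 20)) {
      cuts <- sort(sample(seq(20, total_len - 20), n_exons - 1))
      widths <- diff(c(0, cuts, total_len))
    }
  }
  introns <- if (n_exons > 1) sample(200:1000, n_exons - 1, replace = TRUE) else integer(0)
  starts <- gene_start + cumsum(c(0, widths[-length(widths)] + introns))
  list(start = starts, end = starts + widths)
}

# Map a spliced interval [sp_start, sp_end) back to genomic intervals given
# sorted exon coordinates.
spliced_to_genomic <- function(sp_start, sp_end, ex_start, ex_end) {
  widths <- ex_end - ex_start
  cum <- cumsum(c(0, widths))
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(ex_start)) {
    lo <- max(sp_start, cum[i])
    hi <- min(sp_end, cum[i + 1])
    if (lo < hi) {
      out_s <- c(out_s, ex_start[i] + (lo - cum[i]))
      out_e <- c(out_e, ex_start[i] + (hi - cum[i]))
    }
  }
  list(start = out_s, end = out_e)
}

build_transcript <- function(transcript_id, gene_id, gene_name, strand,
                             gene_start, utr5, cds_len, utr3, n_exons) {
  coding <- cds_len > 0
  total <- if (coding) utr5 + cds_len + utr3 else max(utr5 + utr3, 300)
  ex <- lay_exons(total, n_exons, gene_start)
  # plain data.frame: constructed once per transcript, so keep it cheap
  rows <- data.frame(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    chrom = "chr1", strand = strand, feature = "exon",
    start = ex$start, end = ex$end
  )
  if (coding) {
    # on "+" the 5'UTR occupies the left end of the spliced sequence; on "-"
    # the left end is the 3'UTR
    sp_lo <- if (strand == "+") utr5 else utr3
    cds <- spliced_to_genomic(sp_lo, sp_lo + cds_len, ex$start, ex$end)
    rows <- rbind(rows, data.frame(
      transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
      chrom = "chr1", strand = strand, feature = "CDS",
      start = cds$start, end = cds$end
    ))
  }
  rows
}

#' Simulate transcript annotation with planted switch-pair structure
#'
#' Generates 1-5 isoforms per gene with exon/CDS structures and domain
#' annotations. Within the designated switch genes, isoforms 1 (up) and 2
#' (down) form the planted pair and differ by at least one
#' consequence-relevant feature: a planted exact count of pairs carries a
#' non-coding up-isoform (ORF loss), and the remaining coding pairs carry a
#' 3'UTR shortened (an exact `frac_utr3_shortened` share) or lengthened by
#' 100-300 nt.
#'
#' @param cfg A [sim_config()].
#' @return List with `models` (transcript model tibble), `domains` (domain
#'   side table), `tx_meta` (per-transcript spliced lengths and coding
#'   flags), and `truth`: `switch_genes`, `pairs` (gene_id, up_isoform,
#'   down_isoform, planted consequence label) per planted pair.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    gene_names <- sprintf("GENE%04d", seq_len(cfg$n_genes))
    n_iso <- if (cfg$max_isoforms == 1) rep(1L, cfg$n_genes) else
      sample(seq_len(cfg$max_isoforms), cfg$n_genes, replace = TRUE,
             prob = c(0.25, 0.3, 0.2, 0.15, 0.1)[seq_len(cfg$max_isoforms)])
    multi <- which(n_iso >= 2)
    if (length(multi) < cfg$n_switch_genes) {
      stop("not enough multi-isoform genes to plant switches", call. = FALSE)
    }
    switch_idx <- sort(sample(multi, cfg$n_switch_genes))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE, prob = c(0.8, 0.2))

    n_orf <- round(cfg$frac_orf_loss * cfg$n_switch_genes)
    n_coding_pairs <- cfg$n_switch_genes - n_orf
    n_short <- round(cfg$frac_utr3_shortened * n_coding_pairs)
    # planted consequence per switch gene, as exact counts
    plan <- c(rep("ORF_loss", n_orf), rep("utr3_shortened", n_short),
              rep("utr3_lengthened", n_coding_pairs - n_short))
    plan <- sample(plan)

    rows <- vector("list", cfg$n_genes)
    dom_rows <- list()
    truth_pairs <- list()
    dom_pool <- sprintf("DOM%03d", 1:50)
    for (g in seq_len(cfg$n_genes)) {
      gene_start <- (g - 1) * 20000
      is_switch <- g %in% switch_idx
      planted <- if (is_switch) plan[[match(g, switch_idx)]] else NA_character_
      tx_rows <- vector("list", n_iso[g])
      base_utr3 <- sample(200:600, 1)
      delta <- sample(100:300, 1)
      for (t in seq_len(n_iso[g])) {
        tid <- sprintf("%s.T%d", gene_ids[g], t)
        utr5 <- sample(100:200, 1)
        cds_len <- 3 * sample(100:500, 1)
        utr3 <- sample(200:600, 1)
        coding <- TRUE
        if (is_switch && t == 1) {        # up-isoform
          if (planted == "ORF_loss") {
            coding <- FALSE
          } else if (planted == "utr3_shortened") {
            utr3 <- base_utr3
          } else {
            utr3 <- base_utr3 + delta
          }
        } else if (is_switch && t == 2) { # down-isoform
          if (planted == "utr3_shortened") {
            utr3 <- base_utr3 + delta
          } else if (planted == "utr3_lengthened") {
            utr3 <- base_utr3
          }
        } else if (!is_switch) {
          coding <- stats::runif(1) < 0.8
        }
        if (!coding) cds_len <- 0
        tx_rows[[t]] <- build_transcript(
          tid, gene_ids[g], gene_names[g], strand[g], gene_start,
          utr5, cds_len, utr3, n_exons = sample(1:6, 1)
        )
        if (coding) {
          n_dom <- sample(0:3, 1)
          if (n_dom > 0) {
            doms <- sample(dom_pool, n_dom)
            aa_len <- cds_len %/% 3
            s_aa <- sort(sample(seq_len(max(1, aa_len - 30)), n_dom))
            dom_rows[[length(dom_rows) + 1]] <- data.frame(
              transcript_id = tid, domain_name = doms,
              start_aa = s_aa, end_aa = pmin(aa_len, s_aa + 25)
            )
          }
        }
      }
      rows[[g]] <- dplyr::bind_rows(tx_rows)
      if (is_switch) {
        truth_pairs[[length(truth_pairs) + 1]] <- data.frame(
          gene_id = gene_ids[g],
          up_isoform = sprintf("%s.T1", gene_ids[g]),
          down_isoform = sprintf("%s.T2", gene_ids[g]),
          planted_consequence = planted
        )
      }
    }
    models <- tibble::as_tibble(dplyr::bind_rows(rows))
    domains <- if (length(dom_rows) > 0) tibble::as_tibble(dplyr::bind_rows(dom_rows)) else
      tibble::tibble(transcript_id = character(), domain_name = character(),
                     start_aa = integer(), end_aa = integer())
    tx_meta <- models |>
      dplyr::filter(.data$feature == "exon") |>
      dplyr::group_by(.data$transcript_id, .data$gene_id) |>
      dplyr::summarise(transcript_length = sum(.data$end - .data$start),
                       .groups = "drop")
    list(
      models = models,
      domains = domains,
      tx_meta = tx_meta,
      truth = list(
        switch_genes = gene_ids[switch_idx],
        pairs = if (length(truth_pairs) > 0) tibble::as_tibble(dplyr::bind_rows(truth_pairs))
          else tibble::tibble(gene_id = character(), up_isoform = character(),
                              down_isoform = character(),
                              planted_consequence = character())
      )
    )
  })
}

rdirichlet_one <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

switch_proportions <- function(n_iso, dIF_effect) {
  if (n_iso == 2) {
    pa <- c(0.3, 0.7)
  } else {
    rest <- rep(0.2 / (n_iso - 2), n_iso - 2)
    pa <- c(0.2, 0.6, rest)
  }
  pb <- pa
  pb[1] <- pa[1] + dIF_effect
  pb[2] <- pa[2] - dIF_effect
  list(a = pa, b = pb)
}

#' Simulate transcript abundances with planted antagonistic switches
#'
#' Gene totals per sample are negative binomial around log-normal gene
#' means; per-(gene, sample) isoform usage is Dirichlet around
#' group-specific proportions. In switch genes the melanoma proportions move
#' `dIF_effect` usage mass from the down- to the up-isoform (antagonistic by
#' construction); all other genes share proportions across groups.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List with `abundance` (transcript-by-sample tibble), `samples`
#'   (sample sheet with `sample_id`, `group`, `subtype`), and `truth`:
#'   `proportions` (per switch gene, group proportions of the planted pair)
#'   and `switch_calls` (ground-truth per-sample switch presence for planted
#'   pair members in melanoma samples, using the `tau_switch` rule on the
#'   drawn usage).
#' @export
simulate_expression <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1, {
    samples <- tibble::tibble(
      sample_id = c(sprintf("N%02d", seq_len(cfg$n_nevus)),
                    sprintf("M%02d", seq_len(cfg$n_melanoma))),
      group = c(rep("nevus", cfg$n_nevus), rep("melanoma", cfg$n_melanoma)),
      subtype = c(rep(c("type1", "type2"), length.out = cfg$n_nevus),
                  rep(c("type1", "type2"), length.out = cfg$n_melanoma))
    )
    n_s <- nrow(samples)
    is_mel <- samples$group == "melanoma"
    tx <- ann$tx_meta |> dplyr::arrange(.data$gene_id, .data$transcript_id)
    genes <- unique(tx$gene_id)
    switch_set <- ann$truth$switch_genes

    ab_rows <- vector("list", length(genes))
    call_rows <- list()
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      tids <- tx$transcript_id[tx$gene_id == g]
      n_iso <- length(tids)
      mu <- stats::rlnorm(1, cfg$gene_mean_log, cfg$gene_mean_log_sd)
      totals <- stats::rnbinom(n_s, mu = mu, size = 1 / cfg$nb_dispersion)
      if (g %in% switch_set && n_iso >= 2) {
        pr <- switch_proportions(n_iso, cfg$dIF_effect)
        pa <- pr$a
        pb <- pr$b
      } else {
        pa <- pb <- rdirichlet_one(rep(2, n_iso))
      }
      if (n_iso == 1) {
        usage <- matrix(1, nrow = 1, ncol = n_s)
      } else {
        # per-sample Dirichlet draws via normalized gammas, vectorized over
        # the whole gene at once
        pm <- matrix(pa, nrow = n_iso, ncol = n_s)
        pm[, is_mel] <- pb
        usage <- matrix(stats::rgamma(n_iso * n_s,
                                      shape = cfg$usage_concentration * pm),
                        nrow = n_iso)
        usage <- usage / rep(colSums(usage), each = n_iso)
      }
      ab <- usage * rep(totals, each = n_iso)
      m <- tibble::as_tibble(as.data.frame(ab))
      names(m) <- samples$sample_id
      ab_rows[[gi]] <- dplyr::bind_cols(
        tibble::tibble(transcript_id = tids, gene_id = g), m
      )
      if (g %in% switch_set && n_iso >= 2) {
        dev_up <- usage[1, is_mel] - pa[1]
        dev_down <- usage[2, is_mel] - pa[2]
        call_rows[[length(call_rows) + 1]] <- tibble::tibble(
          transcript_id = rep(tids[1:2], each = sum(is_mel)),
          gene_id = g,
          sample_id = rep(samples$sample_id[is_mel], 2),
          switched = c(dev_up >= cfg$tau_switch, dev_down <= -cfg$tau_switch)
        )
      }
    }
    list(
      abundance = dplyr::bind_rows(ab_rows),
      samples = samples,
      truth = list(
        switch_calls = if (length(call_rows) > 0) dplyr::bind_rows(call_rows)
          else tibble::tibble(transcript_id = character(), gene_id = character(),
                              sample_id = character(), switched = logical())
      )
    )
  })
}

mutation_class_probs <- c(missense = 0.6, synonymous = 0.15, utr3 = 0.1,
                          utr5 = 0.05, nonsense = 0.05, splice_site = 0.05)

#' Simulate per-sample mutation calls with planted structure
#'
#' Baseline per-gene per-sample mutation counts are Poisson with mean
#' `base_mut_rate_per_kb` times the gene's median isoform length in kb —
#' burden scales with gene length, which is what the length-matched
#' backgrounds control for. Melanoma rates of `n_mut_enriched_genes`
#' randomly chosen genes are multiplied by `mut_fold`. For
#' `n_cooccur_isoforms` planted switch up-isoforms, the melanoma samples
#' carrying the ground-truth per-sample switch are mutated in that gene with
#' probability `cooccur_rho` exactly (their baseline draw is overridden);
#' all other samples keep the baseline. Classes follow fixed probabilities
#' (missense 0.6, synonymous 0.15, 3'UTR 0.1, 5'UTR 0.05, nonsense 0.05,
#' splice site 0.05).
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @param expr Output of [simulate_expression()] (supplies the sample sheet
#'   and ground-truth switch calls).
#' @return List with `mutations` (tibble `sample_id`, `gene_id`,
#'   `transcript_id`, `class`, `chrom`, `pos`; `pos` 0-based internally) and
#'   `truth`: `mut_enriched_genes`, `cooccur_isoforms`.
#' @export
simulate_mutations <- function(cfg, ann, expr) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2, {
    samples <- expr$samples
    is_mel <- samples$group == "melanoma"
    lengths <- ann$tx_meta |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(median_length = stats::median(.data$transcript_length),
                       .groups = "drop")
    gene_span <- ann$models |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(lo = min(.data$start), hi = max(.data$end),
                       .groups = "drop")
    genes <- lengths$gene_id
    enriched <- sort(sample(genes, min(cfg$n_mut_enriched_genes, length(genes))))

    up_pool <- expr$truth$switch_calls |>
      dplyr::distinct(.data$transcript_id, .data$gene_id) |>
      dplyr::semi_join(
        tibble::tibble(transcript_id = ann$truth$pairs$up_isoform),
        by = "transcript_id")
    cooccur <- if (nrow(up_pool) > 0 && cfg$n_cooccur_isoforms > 0) {
      up_pool[sort(sample(nrow(up_pool),
                          min(cfg$n_cooccur_isoforms, nrow(up_pool)))), ]
    } else {
      up_pool[0, ]
    }
    cooccur_genes <- cooccur$gene_id

    lam <- cfg$base_mut_rate_per_kb * lengths$median_length / 1000
    counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                     dimnames = list(genes, samples$sample_id))
    for (gi in seq_along(genes)) {
      rate <- rep(lam[gi], nrow(samples))
      if (genes[gi] %in% enriched) rate[is_mel] <- rate[is_mel] * cfg$mut_fold
      counts[gi, ] <- stats::rpois(nrow(samples), rate)
    }
    # co-occurrence override: in planted genes, a melanoma sample's mutated
    # status follows Bernoulli(cooccur_rho) when it carries the switch
    sw <- dplyr::filter(expr$truth$switch_calls,
                        .data$transcript_id %in% cooccur$transcript_id,
                        .data$switched)
    for (i in seq_len(nrow(sw))) {
      g <- sw$gene_id[i]
      s <- sw$sample_id[i]
      mutated <- stats::runif(1) < cfg$cooccur_rho
      counts[g, s] <- if (mutated) max(1L, counts[g, s]) else 0L
    }

    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      muts <- tibble::tibble(sample_id = character(), gene_id = character(),
                             transcript_id = character(), class = character(),
                             chrom = character(), pos = integer())
    } else {
      reps <- counts[idx]
      g_all <- rep(genes[idx[, 1]], reps)
      s_all <- rep(samples$sample_id[idx[, 2]], reps)
      n_mut <- length(g_all)
      span <- gene_span[match(g_all, gene_span$gene_id), ]
      muts <- tibble::tibble(
        sample_id = s_all,
        gene_id = g_all,
        transcript_id = NA_character_,
        class = sample(names(mutation_class_probs), n_mut, replace = TRUE,
                       prob = mutation_class_probs),
        chrom = "chr1",
        pos = as.integer(span$lo + floor(stats::runif(n_mut) * (span$hi - span$lo)))
      ) |>
        dplyr::arrange(.data$sample_id, .data$gene_id, .data$pos)
    }
    list(
      mutations = muts,
      truth = list(mut_enriched_genes = enriched,
                   cooccur_isoforms = cooccur$transcript_id)
    )
  })
}

#' Simulate gene sets including one planted enriched set
#'
#' Emits random gene sets plus one set (`SET_PLANTED`) built mostly from
#' switch genes, so overrepresentation of switched genes is recoverable.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @param n_sets Number of random sets (default 19, plus the planted one).
#' @return Tibble in [read_gmt()] shape.
#' @export
simulate_gene_sets <- function(cfg, ann, n_sets = 19) {
  withr::with_seed(cfg$seed + 3, {
    genes <- unique(ann$tx_meta$gene_id)
    switch_genes <- ann$truth$switch_genes
    rand <- lapply(seq_len(n_sets), function(i) {
      sort(sample(genes, min(length(genes), sample(20:50, 1))))
    })
    n_sw <- min(length(switch_genes), 20)
    other <- setdiff(genes, switch_genes)
    planted <- sort(unique(c(
      sample(switch_genes, n_sw),
      sample(other, min(length(other), 10))
    )))
    tibble::tibble(
      set_id = c(sprintf("SET%03d", seq_len(n_sets)), "SET_PLANTED"),
      name = c(sprintf("random set %d", seq_len(n_sets)), "planted switch set"),
      genes = c(rand, list(planted))
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_annotation()], [simulate_expression()],
#' [simulate_mutations()] and [simulate_gene_sets()] and bundles their
#' outputs with the ground truth needed to score every downstream stage.
#'
#' @param cfg A [sim_config()].
#' @return List: `models`, `domains`, `tx_meta`, `abundance`, `samples`,
#'   `mutations`, `gene_sets`, and `truth` (switch genes/pairs, ground-truth
#'   switch calls, mutation-enriched genes, co-occurrence isoforms).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  mut <- simulate_mutations(cfg, ann, expr)
  sets <- simulate_gene_sets(cfg, ann)
  list(
    models = ann$models,
    domains = ann$domains,
    tx_meta = ann$tx_meta,
    abundance = expr$abundance,
    samples = expr$samples,
    mutations = mut$mutations,
    gene_sets = sets,
    truth = c(ann$truth, expr$truth, mut$truth)
  )
}
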