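test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(seed = 101, n_genes = 25, n_switch_genes = 5,
                    n_cooccur_isoforms = 3, n_mut_enriched_genes = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and different seeds give different data
  c <- simulate_cohort(sim_config(seed = 102, n_genes = 25,
                                  n_switch_genes = 5,
                                  n_cooccur_isoforms = 3,
                                  n_mut_enriched_genes = 3))
  expect_false(identical(a$abundance, c$abundance))
})

test_that("simulated annotation satisfies the transcript model invariants", {
  sim <- simulate_annotation(sim_config(seed = 9, n_genes = 50,
                                        n_switch_genes = 10))
  expect_silent(validate_models(sim$models))
  f <- structural_features(sim$models, sim$domains)
  expect_true(all(f$transcript_length > 0))
  expect_true(all(f$utr5_length + f$utr3_length <= f$transcript_length))
  expect_true(all(f$intron_count >= 0))
  # 1..5 isoforms per gene
  iso_counts <- table(sim$tx_meta$gene_id)
  expect_true(all(iso_counts >= 1 & iso_counts <= 5))

  # planted ORF-loss pairs: down coding, up non-coding
  orf <- dplyr::filter(sim$truth$pairs, planted_consequence == "ORF_loss")
  expect_gt(nrow(orf), 0)
  expect_true(all(!f$coding[match(orf$up_isoform, f$transcript_id)]))
  expect_true(all(f$coding[match(orf$down_isoform, f$transcript_id)]))

  # planted 3'UTR shortening is at least 50 nt and classified as such
  sh <- dplyr::filter(sim$truth$pairs, planted_consequence == "utr3_shortened")
  rec <- classify_switch_consequences(sh, f)
  expect_true(all(vapply(rec$consequences, function(x)
    "utr3_shortened" %in% x, logical(1))))
})

test_that("expression generator plants the configured usage shift", {
  cfg <- sim_config(seed = 23, n_genes = 80, n_switch_genes = 20,
                    dIF_effect = 0.3)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  expect_equal(nrow(expr$samples), 80)
  expect_equal(sum(expr$samples$group == "nevus"), 23)
  expect_equal(sum(expr$samples$group == "melanoma"), 57)

  fr <- isoform_fractions(expr$abundance, epsilon = 1)
  d <- delta_if(fr, expr$samples, c("nevus", "melanoma"))
  up <- ann$truth$pairs$up_isoform
  # planted up-isoforms average near +dIF_effect; Monte-Carlo tolerance
  expect_equal(mean(d$dIF[match(up, d$transcript_id)], na.rm = TRUE), 0.3,
               tolerance = 0.05)
  # non-switch isoforms center on zero
  null_iso <- setdiff(d$transcript_id,
                      c(ann$truth$pairs$up_isoform, ann$truth$pairs$down_isoform))
  expect_lt(abs(mean(d$dIF[match(null_iso, d$transcript_id)], na.rm = TRUE)),
            0.03)

  # dIF_effect 0 -> no systematic shift anywhere
  cfg0 <- sim_config(seed = 23, n_genes = 40, n_switch_genes = 10,
                     dIF_effect = 0)
  ann0 <- simulate_annotation(cfg0)
  expr0 <- simulate_expression(cfg0, ann0)
  d0 <- delta_if(isoform_fractions(expr0$abundance, 1), expr0$samples,
                 c("nevus", "melanoma"))
  up0 <- ann0$truth$pairs$up_isoform
  expect_lt(max(abs(d0$dIF[match(up0, d0$transcript_id)]), na.rm = TRUE), 0.15)
})

test_that("mutation generator scales burden with length, fold and co-occurrence", {
  cfg <- sim_config(seed = 41, n_genes = 150, n_switch_genes = 30,
                    base_mut_rate_per_kb = 0.3, n_mut_enriched_genes = 10,
                    mut_fold = 3, n_cooccur_isoforms = 5, cooccur_rho = 0.9)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  mut <- simulate_mutations(cfg, ann, expr)
  m <- mut$mutations
  validate_models(ann$models)
  expect_true(all(m$class %in% switchscape:::mutation_classes))

  # enriched genes: melanoma per-sample rate is about mut_fold times nevus
  counts <- mutation_counts(m, expr$samples)
  enriched <- mut$truth$mut_enriched_genes
  rate <- counts |>
    dplyr::filter(gene_id %in% enriched) |>
    tidyr::pivot_wider(names_from = group, values_from = n, values_fill = 0) |>
    dplyr::summarise(mel = sum(melanoma) / 57, nev = sum(nevus) / 23)
  expect_equal(rate$mel / rate$nev, 3, tolerance = 0.5)

  # class frequencies near the configured probabilities
  freq <- prop.table(table(m$class))
  expect_equal(unname(freq["missense"]), 0.6, tolerance = 0.05)

  # co-occurrence: switched samples of planted isoforms are mostly mutated
  sw <- expr$truth$switch_calls |>
    dplyr::filter(transcript_id %in% mut$truth$cooccur_isoforms, switched)
  mut_pairs <- dplyr::distinct(m, gene_id, sample_id)
  hit <- dplyr::semi_join(sw, mut_pairs, by = c("gene_id", "sample_id"))
  expect_equal(nrow(hit) / nrow(sw), 0.9, tolerance = 0.1)

  # base rate 0 and no enrichment or co-occurrence -> empty table
  cfg0 <- sim_config(seed = 41, n_genes = 20, n_switch_genes = 2,
                     base_mut_rate_per_kb = 0, n_mut_enriched_genes = 0,
                     n_cooccur_isoforms = 0)
  ann0 <- simulate_annotation(cfg0)
  expr0 <- simulate_expression(cfg0, ann0)
  mut0 <- simulate_mutations(cfg0, ann0, expr0)
  expect_equal(nrow(mut0$mutations), 0)
})
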