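test_that("expression filter removes low-mean transcripts and empty genes", {
  m <- rbind(c(0.1, 0.1, 0.1), c(4, 5, 6), c(18, 20, 22),
             c(0.2, 0.1, 0.3), c(0.5, 0.4, 0.6))
  rownames(m) <- c("t1", "t2", "t3", "t4", "t5")
  ab <- toy_abundance(m, gene_ids = c("gA", "gA", "gA", "gB", "gB"))
  # thresholds 0 -> identity
  expect_identical(filter_low_expression(ab, 0), ab)
  out <- filter_low_expression(ab, 1)
  expect_setequal(out$transcript_id, c("t2", "t3"))
  # gene whose isoforms all fail disappears entirely
  expect_false("gB" %in% out$gene_id)
  expect_error(filter_low_expression(ab, 1000), "survive")
})

test_that("isoform fractions normalize per gene and respect the epsilon rule", {
  m <- rbind(c(30, 0, 100), c(70, 0, 0))
  rownames(m) <- c("t1", "t2")
  ab <- toy_abundance(m, gene_ids = c("g1", "g1"))
  fr <- isoform_fractions(ab, epsilon = 1)
  expect_equal(fr$s1, c(0.3, 0.7))
  # zero gene expression -> both fractions missing
  expect_true(all(is.na(fr$s2)))
  # single expressed isoform -> fraction 1
  expect_equal(fr$s3, c(1, 0))

  # conservation property on a simulated dataset
  sim <- simulate_cohort(sim_config(seed = 3, n_genes = 40, n_switch_genes = 6))
  fr2 <- isoform_fractions(sim$abundance, epsilon = 1)
  cols <- setdiff(names(fr2), c("transcript_id", "gene_id"))
  sums <- rowsum(as.matrix(fr2[cols]), group = fr2$gene_id, na.rm = TRUE)
  present <- rowsum((!is.na(as.matrix(fr2[cols]))) * 1, group = fr2$gene_id)
  expect_true(all(abs(sums[present > 0] - 1) < 1e-9))
})

test_that("dIF is the group mean difference and sums to zero within genes", {
  s <- toy_samples(2, 2)
  fr <- toy_abundance(rbind(c(0.2, 0.2, 0.6, 0.6), c(0.8, 0.8, 0.4, 0.4)),
                      gene_ids = c("g1", "g1"), sample_ids = s$sample_id)
  d <- delta_if(fr, s, c("nevus", "melanoma"))
  expect_equal(d$dIF, c(0.4, -0.4))
  expect_equal(sum(d$dIF), 0)

  # swapping the contrast negates dIF
  d2 <- delta_if(fr, s, c("melanoma", "nevus"))
  expect_equal(d2$dIF, -d$dIF)

  # identical group means -> 0
  fr0 <- toy_abundance(rbind(c(0.5, 0.5, 0.5, 0.5), c(0.5, 0.5, 0.5, 0.5)),
                       gene_ids = c("g1", "g1"), sample_ids = s$sample_id)
  expect_equal(delta_if(fr0, s, c("nevus", "melanoma"))$dIF, c(0, 0))
})

test_that("permutation test: ties give p = 1, planted switches are significant", {
  s <- toy_samples(10, 10)
  withr::with_seed(11, {
    # constant isoforms: every permuted |dIF| ties the observed 0
    const <- toy_abundance(matrix(0.5, 2, 20, dimnames = list(c("t1", "t1b"), NULL)),
                           gene_ids = c("g1", "g1"),
                           sample_ids = s$sample_id)
    # planted switch: dIF 0.5, within-group sd 0.05
    f_a <- pmin(pmax(stats::rnorm(10, 0.2, 0.05), 0), 1)
    f_b <- pmin(pmax(stats::rnorm(10, 0.7, 0.05), 0), 1)
    sw <- toy_abundance(rbind(c(f_a, f_b), 1 - c(f_a, f_b)),
                        gene_ids = c("g2", "g2"),
                        sample_ids = s$sample_id)
    sw$transcript_id <- c("t2", "t3")
  })
  fr <- dplyr::bind_rows(const, sw)
  p <- permutation_test_dtu(fr, s, c("nevus", "melanoma"),
                            n_perm = 999, seed = 5)
  expect_equal(p$p_value[p$transcript_id == "t1"], 1)
  expect_lte(p$p_value[p$transcript_id == "t2"], 0.01)

  # same seed -> identical p-values; group swap -> unchanged p-values
  p2 <- permutation_test_dtu(fr, s, c("nevus", "melanoma"),
                             n_perm = 999, seed = 5)
  expect_identical(p$p_value, p2$p_value)
  p3 <- permutation_test_dtu(fr, s, c("melanoma", "nevus"),
                             n_perm = 999, seed = 5)
  expect_equal(p3$p_value, p$p_value)
  expect_equal(p3$dIF, -p$dIF)
})

test_that("BH adjustment matches the step-up formula and passes NA through", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.007), 0.007)
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  # NA entries do not count toward m
  expect_equal(q[c(1, 3)], stats::p.adjust(c(0.01, 0.02), "BH"))
})

test_that("switch pair calling applies the antagonistic rule", {
  tests <- tibble::tibble(
    transcript_id = c("t1", "t2"), gene_id = "g1",
    dIF = c(0.3, -0.3), p_value = c(0.001, 0.15),
    q_value = c(0.001, 0.2)
  )
  pairs <- call_switch_pairs(tests, dIF_threshold = 0.1, q_threshold = 0.05)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$up_isoform, "t1")
  expect_equal(pairs$down_isoform, "t2")

  # both q above threshold -> nothing
  tests$q_value <- c(0.2, 0.3)
  expect_equal(nrow(call_switch_pairs(tests)), 0)

  # |dIF| below threshold excludes a member even when significant
  tests3 <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"), gene_id = "g1",
    dIF = c(0.3, -0.2, -0.05), p_value = c(0.001, 0.002, 0.003),
    q_value = c(0.01, 0.01, 0.01)
  )
  pairs3 <- call_switch_pairs(tests3, dIF_threshold = 0.1)
  expect_equal(nrow(pairs3), 1)
  expect_equal(pairs3$down_isoform, "t2")

  # output invariant to isoform input order
  pairs3b <- call_switch_pairs(tests3[c(3, 1, 2), ], dIF_threshold = 0.1)
  expect_identical(pairs3, pairs3b)
})

test_that("gene-level q aggregates min-p with Bonferroni scaling", {
  tests <- tibble::tibble(
    transcript_id = paste0("t", 1:5),
    gene_id = c("g1", rep("g2", 4)),
    p_value = c(0.01, 0.002, 0.5, 0.6, 0.7)
  )
  g <- gene_switch_qvalue(tests)
  expect_equal(g$gene_p[g$gene_id == "g1"], 0.01)
  expect_equal(g$gene_p[g$gene_id == "g2"], 0.008)
  expect_equal(g$gene_q, bh_adjust(g$gene_p))

  solo <- gene_switch_qvalue(tibble::tibble(transcript_id = "t", gene_id = "g",
                                            p_value = 0.01))
  expect_equal(solo$gene_q, 0.01)
})

test_that("per-sample switch calls follow the direction-and-threshold rule", {
  # group A mean fraction 0.2; samples b1..b3 at 0.7, 0.2, 0.05
  fr <- toy_abundance(rbind(c(0.2, 0.2, 0.7, 0.2, 0.05),
                            c(0.8, 0.8, 0.3, 0.8, 0.95)),
                      gene_ids = c("g1", "g1"),
                      sample_ids = c("a1", "a2", "b1", "b2", "b3"))
  fr$transcript_id <- c("t1", "t2")
  s <- toy_samples(2, 3)
  pairs <- tibble::tibble(gene_id = "g1", up_isoform = "t1",
                          down_isoform = "t2", dIF_up = 0.4, dIF_down = -0.4,
                          p_up = 0.001, p_down = 0.001,
                          q_up = 0.01, q_down = 0.01)
  calls <- per_sample_switch_calls(fr, pairs, s, c("nevus", "melanoma"),
                                   tau_switch = 0.1)
  up <- dplyr::filter(calls, transcript_id == "t1")
  expect_equal(up$switched[match(c("b1", "b2", "b3"), up$sample_id)],
               c(TRUE, FALSE, FALSE))  # b2 equals the mean, b3 goes opposite
  down <- dplyr::filter(calls, transcript_id == "t2")
  expect_equal(down$switched[match(c("b1", "b2", "b3"), down$sample_id)],
               c(TRUE, FALSE, FALSE))
})

test_that("detect_switches recovers a planted switch end to end", {
  sim <- simulate_cohort(sim_config(seed = 21, n_genes = 60,
                                    n_switch_genes = 8))
  fit <- detect_switches(sim$abundance, sim$samples,
                         contrast = c("nevus", "melanoma"),
                         n_perm = 499, seed = 42)
  expect_s3_class(fit, "switch_fit")
  found <- unique(fit$pairs$gene_id)
  expect_gte(length(intersect(found, sim$truth$switch_genes)), 6)
  expect_true(all(c("gene_q") %in% names(fit$pairs)))
  td <- tidy(fit)
  expect_identical(td, fit$pairs)
  gl <- glance(fit)
  expect_equal(gl$n_switch_pairs, nrow(fit$pairs))
  expect_s3_class(autoplot(fit), "ggplot")
})
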