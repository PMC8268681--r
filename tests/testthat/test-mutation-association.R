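toy_muts <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sample_id = vapply(rows, `[[`, character(1), 1),
    gene_id = vapply(rows, `[[`, character(1), 2),
    class = vapply(rows, `[[`, character(1), 3)
  )
}

test_that("mutation counts respect class filters and count every record", {
  s <- toy_samples(2, 3)
  m <- toy_muts(
    list("b1", "G", "missense"), list("b1", "G", "missense"),
    list("b2", "G", "missense"), list("b3", "G", "utr3")
  )
  all_counts <- mutation_counts(m, s)
  expect_equal(all_counts$n[all_counts$gene_id == "G" &
                              all_counts$group == "melanoma"], 4)
  coding <- mutation_counts(m, s, class_filter = coding_mutation_classes)
  expect_equal(coding$n[coding$group == "melanoma"], 3)
  # empty table -> no rows
  expect_equal(nrow(mutation_counts(m[0, ], s)), 0)
  # unknown class -> loud error
  bad <- toy_muts(list("b1", "G", "frameshift"))
  expect_error(mutation_counts(bad, s), "frameshift")
})

test_that("average count difference is per-sample normalized", {
  s <- toy_samples(23, 57)
  m <- dplyr::bind_rows(
    tibble::tibble(sample_id = paste0("b", 1:57), gene_id = "G1",
                   class = "missense"),
    tibble::tibble(sample_id = paste0("a", 1:23), gene_id = "G2",
                   class = "missense")
  )
  counts <- mutation_counts(m, s)
  d <- average_count_difference(counts, s, c("nevus", "melanoma"),
                                genes = c("G1", "G2", "G3"))
  expect_equal(d$delta[d$gene_id == "G1"], 1)
  expect_equal(d$delta[d$gene_id == "G2"], -1)
  expect_equal(d$delta[d$gene_id == "G3"], 0)  # unmutated genes pad to zero
})

test_that("length matching honors the window, top-up and determinism", {
  lengths <- tibble::tibble(
    gene_id = c("q", "in1", "in2", "in3", "out_far", "out_near"),
    median_length = c(1000, 900, 1100, 1050, 5000, 1500)
  )
  # 1500 is outside a +/-20% window of 1000 (|log 1.5| > log 1.2)
  got <- length_matched_genes("q", lengths, k = 3, window = 0.2, seed = 1)
  expect_setequal(got, c("in1", "in2", "in3"))
  # top-up takes the nearest gene outside the window
  got4 <- length_matched_genes("q", lengths, k = 4, window = 0.2, seed = 1)
  expect_true("out_near" %in% got4)
  expect_false("out_far" %in% got4)
  # determinism
  expect_identical(
    length_matched_genes("q", lengths, k = 3, window = 0.2, seed = 7),
    length_matched_genes("q", lengths, k = 3, window = 0.2, seed = 7))
  expect_error(length_matched_genes("q", lengths, k = 10, seed = 1), "pool")
})

test_that("gene mutation z-score is location/scale invariant and flags outliers", {
  withr::with_seed(5, {
    lengths <- tibble::tibble(gene_id = sprintf("g%03d", 1:50),
                              median_length = stats::runif(50, 900, 1100))
    deltas <- tibble::tibble(gene_id = lengths$gene_id,
                             delta = stats::rnorm(50, 0.1, 0.2))
  })
  deltas$delta[1] <- 0.9
  z <- gene_mutation_zscore("g001", deltas, lengths, k = 40, seed = 2)
  expect_equal(z$z, (z$delta - z$bg_mean) / z$bg_sd)
  # arithmetic example: delta 0.9, bg mean 0.1, bg sd 0.2 -> z = 4
  z_manual <- (0.9 - 0.1) / 0.2
  expect_equal(z_manual, 4)
  # shifting or scaling all deltas leaves z unchanged
  shifted <- dplyr::mutate(deltas, delta = delta + 5)
  scaled <- dplyr::mutate(deltas, delta = delta * 3)
  z_s <- gene_mutation_zscore("g001", shifted, lengths, k = 40, seed = 2)
  z_c <- gene_mutation_zscore("g001", scaled, lengths, k = 40, seed = 2)
  expect_equal(z$z, z_s$z, tolerance = 1e-9)
  expect_equal(z$z, z_c$z, tolerance = 1e-9)
  # delta equal to the background mean -> z near 0, not significant
  deltas0 <- dplyr::mutate(deltas, delta = 0.1)
  z0 <- gene_mutation_zscore("g001", deltas0, lengths, k = 40, seed = 2)
  expect_equal(z0$z, 0)
  expect_false(z0$significant)
  expect_true(z0$degenerate)
})

test_that("jaccard index matches brute force and its edge conventions", {
  expect_equal(jaccard_index(c("s1", "s2", "s3"), c("s2", "s3", "s4")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 0)
  # symmetry on random subsets
  withr::with_seed(8, {
    u <- paste0("s", 1:12)
    for (i in 1:25) {
      a <- sample(u, sample(0:12, 1))
      b <- sample(u, sample(0:12, 1))
      expect_equal(jaccard_index(a, b), jaccard_index(b, a))
      # independent bit-vector oracle
      va <- u %in% a
      vb <- u %in% b
      oracle <- if (sum(va | vb) == 0) 0 else sum(va & vb) / sum(va | vb)
      expect_equal(jaccard_index(a, b), oracle)
    }
  })
})

test_that("mutated sample fraction counts samples, not records", {
  m <- toy_muts(list("b1", "G", "missense"), list("b1", "G", "nonsense"),
                list("b2", "G", "utr3"))
  tumor <- paste0("b", 1:3)
  expect_equal(mutated_sample_fraction("G", m, tumor), 2 / 3)
  expect_equal(mutated_sample_fraction("G", m, tumor,
                                       class_filter = coding_mutation_classes),
               2 / 3 - 1 / 3)
  expect_equal(mutated_sample_fraction("other", m, tumor), 0)
})

test_that("jaccard z-score separates planted co-occurrence from background", {
  # 60 switched isoforms; 5 planted with mutation sets equal to their switch
  # sets, background with independent mutations
  withr::with_seed(17, {
    tumor <- sprintf("M%02d", 1:57)
    iso <- sprintf("iso%03d", 1:60)
    genes <- sprintf("gene%03d", 1:60)
    calls <- list()
    muts <- list()
    for (i in 1:60) {
      sw <- sample(tumor, 40)
      switched <- tumor %in% sw
      calls[[i]] <- tibble::tibble(transcript_id = iso[i], gene_id = genes[i],
                                   sample_id = tumor, switched = switched)
      mut_samples <- if (i <= 5) sw else sample(tumor, 10)
      muts[[i]] <- tibble::tibble(sample_id = mut_samples, gene_id = genes[i],
                                  class = "missense")
    }
  })
  calls <- dplyr::bind_rows(calls)
  muts <- dplyr::bind_rows(muts)
  features <- tibble::tibble(transcript_id = iso, gene_id = genes,
                             transcript_length = 1000)
  res <- jaccard_zscore(calls, muts, tumor, features, k = 50, seed = 3)
  expect_true(all(res$significant[1:5]))
  expect_lt(mean(res$significant[6:60]), 0.2)
  expect_true(all(res$j >= 0 & res$j <= 1))
  # planted isoforms have J = 1 by construction
  expect_equal(res$j[1:5], rep(1, 5))
  # determinism
  res2 <- jaccard_zscore(calls, muts, tumor, features, k = 50, seed = 3)
  expect_identical(res, res2)
})
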