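# a small but non-trivial shared fixture: reference + models + capture
perm_fixture <- function(seed = 13, n_genes = 6, burden = 3,
                         hotspots = list(), n_validation = 0L) {
  cfg <- cohort_config(seed = seed, n_genes = n_genes,
                       burden_median = burden, n_validation = n_validation,
                       hotspots = hotspots)
  coh <- generate_cohort(cfg)
  flt <- filter_variants(coh$variants, regions = coh$regions,
                         panel = coh$panel)
  ann <- annotate_variants(flt$variants, coh$models, coh$ref)
  index <- build_site_index(coh$ref, coh$regions)
  c(coh, list(annotated = ann, index = index))
}

test_that("site index partitions capture bases by source base and CpG", {
  ref <- dna_reference(c(c1 = "ACGTT"))
  regions <- capture_regions("c1", 1L, 5L)
  idx <- build_site_index(ref, regions)
  # C at position 2 is followed by G: the only CpG C
  expect_equal(eligible_sites(idx, "C>T (at CpG)")$pos, 2L)
  expect_equal(eligible_sites(idx, "C>T (not at CpG)")$pos, integer(0))
  expect_equal(eligible_sites(idx, "G>A (at CpG)")$pos, 3L)
  # the three A>* types share the A sites
  for (t in c("A>C", "A>G", "A>T"))
    expect_equal(eligible_sites(idx, t)$pos, 1L)
  expect_equal(eligible_sites(idx, "T>C")$pos, c(4L, 5L))
  # every capture base appears in the class of its own base/context
  expect_equal(sum(vapply(hotspotr:::.site_class_levels(),
                          function(cl) length(idx$by_class[[cl]]),
                          integer(1))),
               5L)
  # a sequence with no G leaves all CpG C-source classes empty
  idx2 <- build_site_index(dna_reference(c(c1 = "ACCTA")),
                           capture_regions("c1", 1L, 5L))
  expect_equal(nrow(eligible_sites(idx2, "C>A (at CpG)")), 0L)
  expect_error(build_site_index(ref, capture_regions(character(0),
                                                     integer(0),
                                                     integer(0))),
               "empty capture")
})

test_that("N bases are excluded from the site index", {
  idx <- build_site_index(dna_reference(c(c1 = "ANGT")),
                          capture_regions("c1", 1L, 4L))
  expect_equal(nrow(idx$sites), 3L)
  expect_false(any(idx$sites$base == "N"))
})

test_that("randomization preserves counts, labels and the type multiset", {
  fx <- perm_fixture()
  ann <- fx$annotated
  set.seed(1)
  for (round in 1:5) {
    rnd <- permute_once(ann, fx$index, fx$models, fx$ref)
    # synthetic genes do not overlap, so both tables have one row per
    # mutation: counts, sample labels and the 18-type multiset are conserved
    expect_equal(nrow(rnd), nrow(ann))
    expect_equal(sort(rnd$mutation_type), sort(ann$mutation_type))
    expect_equal(sort(rnd$sample_id), sort(ann$sample_id))
    expect_equal(sort(paste(rnd$sample_id, rnd$mutation_type)),
                 sort(paste(ann$sample_id, ann$mutation_type)))
    # every placement lands on a site eligible for its type
    for (t in unique(rnd$mutation_type)) {
      ok <- eligible_sites(fx$index, t)$pos
      expect_true(all(rnd$pos[rnd$mutation_type == t] %in% ok))
    }
  }
})

test_that("single eligible site forces placement; two sites split evenly", {
  # contig with exactly one C (no CpG) and two A's
  ref <- dna_reference(c(c1 = "ATCTA"))
  regions <- capture_regions("c1", 1L, 5L)
  idx <- build_site_index(ref, regions)
  mut_c <- annotated_row("s1", NA_character_, NA, "noncoding")
  mut_c$mutation_type <- "C>T (not at CpG)"
  gm <- gene_model("g", "g.t1", "c1", "+", cbind(1L, 3L))
  set.seed(4)
  rnd <- permute_once(mut_c, idx, list(gm), ref)
  expect_equal(unique(rnd$pos), 3L)  # the only eligible C
  # binomial check on a 2-site pool
  mut_a <- mut_c
  mut_a$mutation_type <- "A>G"
  set.seed(9)
  hits <- replicate(4000, {
    permute_once(mut_a, idx, list(gm), ref)$pos[1]
  })
  p1 <- mean(hits == 1L)
  expect_true(abs(p1 - 0.5) < 3 * sqrt(0.25 / 4000))
  # a type with zero eligible sites errors by name
  mut_bad <- mut_c
  mut_bad$mutation_type <- "C>T (at CpG)"
  expect_error(permute_once(mut_bad, idx, list(gm), ref),
               "C>T \\(at CpG\\)")
})

test_that("null criterion counts non-synonymous mutations, not samples", {
  ann <- rbind(annotated_row("s1", "g", 5),
               annotated_row("s1", "g", 5))
  expect_equal(count_null_hotspots(ann), 1L)  # 2 mutations, 1 sample
  expect_equal(count_hotspot_clusters(ann, criterion = "samples"), 0L)
  syn <- rbind(annotated_row("s1", "g", 5, "synonymous"),
               annotated_row("s2", "g", 5, "synonymous"))
  expect_equal(count_null_hotspots(syn), 0L)
  chain <- rbind(annotated_row("s1", "g", 5),
                 annotated_row("s2", "g", 6),
                 annotated_row("s3", "g", 7))
  expect_equal(count_null_hotspots(chain), 1L)  # merged component
  splice <- rbind(annotated_row("s1", "g", NA, "splice_site", boundary = 10),
                  annotated_row("s2", "g", NA, "splice_site", boundary = 10))
  expect_equal(count_null_hotspots(splice), 0L)  # excluded from the null
})

test_that("cluster counting matches the oracle on random inputs", {
  set.seed(55)
  for (rep in 1:300) {
    ann <- random_annotated(n = sample(2:15, 1))
    expect_equal(count_hotspot_clusters(ann, criterion = "mutations"),
                 oracle_count_clusters(ann, criterion = "mutations"))
    expect_equal(count_hotspot_clusters(ann, criterion = "samples"),
                 oracle_count_clusters(ann, criterion = "samples"))
  }
})

test_that("fast permutation rounds equal the slow re-annotation route", {
  fx <- perm_fixture(seed = 21, n_genes = 5, burden = 2)
  ann <- fx$annotated
  R <- 15L
  res <- run_permutation_test(ann, fx$index, fx$models, fx$ref, R = R,
                              seed = 99)
  set.seed(99)
  slow <- vapply(seq_len(R), function(r) {
    count_null_hotspots(permute_once(ann, fx$index, fx$models, fx$ref))
  }, integer(1))
  expect_identical(res$null_counts, slow)
  # determinism: same seed, same null vector
  res2 <- run_permutation_test(ann, fx$index, fx$models, fx$ref, R = R,
                               seed = 99)
  expect_identical(res$null_counts, res2$null_counts)
})

test_that("p-value convention: add-one, two-sided, capped at 1", {
  fake <- function(obs, nulls) {
    b_ge <- sum(nulls >= obs); b_le <- sum(nulls <= obs)
    min(1, 2 * min(b_ge + 1, b_le + 1) / (length(nulls) + 1))
  }
  # hand-counted: nulls {5,7,9,11}, observed 10 -> b_ge 1, b_le 3, p 0.8
  expect_equal(fake(10, c(5, 7, 9, 11)), 0.8)
  # all nulls below observed at R = 100,000 -> 2/100001 -> 2e-5 at 2 s.f.
  expect_equal(signif(fake(50, rep(0, 100000)), 2), 2e-5)
  # observed equal to every null: capped at 1
  expect_equal(fake(3, rep(3, 100)), 1)
  # the implementation reproduces the same convention end to end
  fx <- perm_fixture(seed = 3, n_genes = 4, burden = 1)
  res <- run_permutation_test(fx$annotated, fx$index, fx$models, fx$ref,
                              R = 50, seed = 7)
  expect_equal(res$p_two_sided,
               min(1, 2 * min(res$b_ge + 1, res$b_le + 1) / 51))
  expect_gt(res$p_two_sided, 0)
  expect_lte(res$p_two_sided, 1)
  expect_error(run_permutation_test(fx$annotated, fx$index, fx$models,
                                    fx$ref, R = 0), "at least 1")
})

test_that("p-values are calibrated when the observed set is itself null", {
  fx <- perm_fixture(seed = 17, n_genes = 4, burden = 2)
  ann <- fx$annotated
  set.seed(123)
  reps <- 500L
  pvals <- vapply(seq_len(reps), function(i) {
    obs <- permute_once(ann, fx$index, fx$models, fx$ref)
    run_permutation_test(obs, fx$index, fx$models, fx$ref,
                         R = 200L)$p_two_sided
  }, numeric(1))
  # the two-sided p of a discrete statistic is super-uniform under its own
  # null: P(p <= a) must not exceed a (within Monte Carlo error), and the
  # distribution must not be degenerate at either extreme
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / reps) + 0.01,
               label = paste("alpha", a))
  }
  expect_gt(mean(pvals), 0.3)
  expect_gt(stats::sd(pvals), 0.01)
})
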