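test_that("same-codon, adjacent-codon and merged clusters are detected", {
  # same codon, two samples
  ann <- rbind(annotated_row("s1", "STK38L", 105),
               annotated_row("s2", "STK38L", 105))
  hs <- detect_hotspots(ann)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$kind, "same_codon")
  expect_equal(c(hs$codon_min, hs$codon_max), c(105L, 105L))
  # adjacent codons, two samples (Arg347Trp / Arg348Cys pattern)
  ann <- rbind(annotated_row("s1", "TROAP", 347),
               annotated_row("s2", "TROAP", 348))
  hs <- detect_hotspots(ann)
  expect_equal(hs$kind, "adjacent_codon")
  # synonymous pairs never qualify
  ann <- rbind(annotated_row("s1", "g", 10, "synonymous"),
               annotated_row("s2", "g", 10, "synonymous"))
  expect_equal(nrow(detect_hotspots(ann)), 0L)
  # five substitutions across two adjacent codons merge into one hot spot
  ann <- rbind(annotated_row("s1", "PIK3CA", 545),
               annotated_row("s2", "PIK3CA", 545),
               annotated_row("s3", "PIK3CA", 546),
               annotated_row("s4", "PIK3CA", 546),
               annotated_row("s5", "PIK3CA", 546))
  hs <- detect_hotspots(ann)
  expect_equal(nrow(hs), 1L)
  expect_equal(c(hs$codon_min, hs$codon_max), c(545L, 546L))
  expect_equal(hs$n_mutations, 5L)
  # two mutations in one codon of one sample: not recurrent across samples
  ann <- rbind(annotated_row("s1", "g", 7), annotated_row("s1", "g", 7))
  expect_equal(nrow(detect_hotspots(ann, min_samples = 2)), 0L)
})

test_that("splice-flank clusters key on the exon boundary", {
  ann <- rbind(annotated_row("s1", "g", NA, "splice_site", boundary = 600),
               annotated_row("s2", "g", NA, "splice_site", boundary = 600),
               annotated_row("s3", "g", NA, "splice_site", boundary = 900))
  hs <- detect_hotspots(ann)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$kind, "splice_flank")
  expect_equal(hs$boundary_pos, 600L)
})

test_that("denylisted genes are omitted unless requested", {
  ann <- rbind(annotated_row("s1", "BRAF", 600),
               annotated_row("s2", "BRAF", 600),
               annotated_row("s1", "NEW", 10),
               annotated_row("s2", "NEW", 10))
  hs <- detect_hotspots(ann, denylist = "BRAF")
  expect_equal(hs$gene_id, "NEW")
  hs_all <- detect_hotspots(ann, denylist = "BRAF",
                            include_denylisted = TRUE)
  expect_setequal(hs_all$gene_id, c("BRAF", "NEW"))
  expect_true(hs_all$denylisted[hs_all$gene_id == "BRAF"])
})

test_that("detector equals the brute-force connected-component oracle", {
  set.seed(2024)
  for (rep in 1:1000) {
    ann <- random_annotated()
    hs <- detect_hotspots(ann)
    expect_identical(detected_signature(hs, ann), oracle_hotspots(ann),
                     label = paste("rep", rep))
  }
})

test_that("adding a mutation never removes a hot spot (monotonicity)", {
  set.seed(77)
  for (rep in 1:100) {
    ann <- random_annotated(n = sample(4:10, 1))
    bigger <- rbind(ann, random_annotated(n = 1))
    big_hs <- detect_hotspots(bigger)
    # every hot spot of the smaller set survives (possibly merged into a
    # larger cluster): each member set stays inside some detected cluster
    base_hs <- detect_hotspots(ann)
    for (i in seq_len(nrow(base_hs))) {
      members <- base_hs$rows[[i]]
      contained <- any(vapply(seq_len(nrow(big_hs)), function(j) {
        all(members %in% big_hs$rows[[j]])
      }, logical(1)))
      expect_true(contained)
    }
    # and removing a mutation never creates one: every hot spot of the
    # reduced set already existed inside a hot spot of the full set
    if (nrow(ann) > 1) {
      drop <- sample(nrow(ann), 1)
      smaller <- ann[-drop, , drop = FALSE]
      small_hs <- detect_hotspots(smaller)
      orig_idx <- seq_len(nrow(ann))[-drop]  # map reduced rows back
      for (i in seq_len(nrow(small_hs))) {
        members <- orig_idx[small_hs$rows[[i]]]
        contained <- any(vapply(seq_len(nrow(base_hs)), function(j) {
          all(members %in% base_hs$rows[[j]])
        }, logical(1)))
        expect_true(contained)
      }
    }
  }
})

test_that("members lie within the emitted codon span and kinds partition", {
  set.seed(31)
  for (rep in 1:200) {
    ann <- random_annotated(n = sample(4:14, 1))
    hs <- detect_hotspots(ann)
    for (i in seq_len(nrow(hs))) {
      rows <- hs$rows[[i]]
      if (hs$kind[i] == "splice_flank") {
        expect_true(all(is.na(ann$codon_index[rows])))
      } else {
        expect_true(all(ann$codon_index[rows] >= hs$codon_min[i] &
                          ann$codon_index[rows] <= hs$codon_max[i]))
      }
    }
    expect_equal(sum(hs$kind == "same_codon") +
                   sum(hs$kind == "adjacent_codon") +
                   sum(hs$kind == "splice_flank"), nrow(hs))
  }
})

test_that("gene-level recurrence rule counts tumors, not mutations", {
  two_tumors <- rbind(annotated_row("s1", "g1", 5),
                      annotated_row("s2", "g1", 9))
  three_tumors <- rbind(two_tumors, annotated_row("s3", "g1", 20))
  one_tumor_many <- do.call(rbind, lapply(1:5, function(i)
    annotated_row("s1", "g2", i * 3)))
  expect_equal(exclude_low_recurrence_genes(two_tumors), character(0))
  expect_equal(exclude_low_recurrence_genes(three_tumors), "g1")
  expect_equal(exclude_low_recurrence_genes(one_tumor_many), character(0))
  # silent mutations do not count toward recurrence
  silent <- do.call(rbind, lapply(1:4, function(i)
    annotated_row(paste0("s", i), "g3", 7, "synonymous")))
  expect_equal(exclude_low_recurrence_genes(silent), character(0))
})

test_that("cohort frequency arithmetic rounds half-up to one decimal", {
  f <- compute_frequencies(10, 32, cohort_sizes = c(36L, 93L),
                           hotspot_mutations = 42, gene_mutations = 45)
  expect_equal(f$n_total, 42)
  expect_equal(f$pct_discovery, 27.8)
  expect_equal(f$pct_validation, 34.4)
  expect_equal(f$pct_total, 32.6)
  expect_equal(f$hotspot_fraction, "42/45")
  expect_equal(f$hotspot_fraction_pct, 93.3)
  expect_equal(compute_frequencies(0, 0)$pct_total, 0.0)
  expect_equal(compute_frequencies(2, 2)$pct_discovery, 5.6)
  expect_error(compute_frequencies(1, 1, cohort_sizes = c(0L, 93L)),
               "positive")
  # half-up, not banker's rounding
  expect_equal(round_half_up(27.75, 1), 27.8)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("two-stage detection flags validation-emergent hot spots", {
  ann <- rbind(
    annotated_row("d1", "g1", 50, cohort = "discovery"),
    annotated_row("d2", "g1", 50, cohort = "discovery"),
    annotated_row("v1", "g1", 50, cohort = "validation"),
    annotated_row("v1", "g2", 7, cohort = "validation"),
    annotated_row("v2", "g2", 8, cohort = "validation"))
  hs <- detect_hotspots_staged(ann, cohort_sizes = c(36L, 93L))
  g1 <- hs[hs$gene_id == "g1", ]
  g2 <- hs[hs$gene_id == "g2", ]
  expect_false(g1$validation_emergent)
  expect_true(g2$validation_emergent)
  expect_equal(g1$n_discovery, 2L)
  expect_equal(g1$n_validation, 1L)
  expect_equal(g1$pct_discovery, 5.6)
  expect_equal(g1$pct_validation, 1.1)
  expect_equal(g1$pct_total, 2.3)
})

test_that("external rankings join by gene with missing markers", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"))
  rk <- list(fml = data.frame(gene = c("g1", "g3"), rank = c(1L, 7L)),
             cv = data.frame(gene = "g2", rank = 4L))
  out <- rank_merge_report(genes, rk)
  expect_equal(out$standing_fml, c(1L, NA, 7L))
  expect_equal(out$standing_cv, c(NA, 4L, NA))
  expect_equal(rank_merge_report(genes, list()), genes)
  dup <- list(fml = data.frame(gene = c("g1", "g1"), rank = 1:2))
  expect_error(rank_merge_report(genes, dup), "duplicate")
})
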