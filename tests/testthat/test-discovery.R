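aln_gr <- function(starts, widths, strands, tags) {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(starts, width = widths),
                               strand = strands)
  gr$tag <- tags
  gr$n_hits <- 1L
  gr
}

tagtab <- function(tags, counts) {
  data.frame(sequence = tags, L1 = counts, stringsAsFactors = FALSE)
}

test_that("clustering merges nearby same-strand tags only", {
  aln <- aln_gr(c(100, 127), c(22, 22), c("+", "+"), c("AAA", "CCC"))
  cl <- cluster_unannotated(aln, tagtab(c("AAA", "CCC"), c(5, 3)))
  expect_equal(length(cl), 1L) # 5-nt gap: one cluster
  expect_equal(cl$mature, "AAA") # most abundant tag is the mature
  aln2 <- aln_gr(c(100, 127), c(22, 22), c("+", "-"), c("AAA", "CCC"))
  cl2 <- cluster_unannotated(aln2, tagtab(c("AAA", "CCC"), c(5, 3)))
  expect_equal(length(cl2), 2L) # opposite strands never merge
  aln3 <- aln_gr(c(100, 160), c(22, 22), c("+", "+"), c("AAA", "CCC"))
  cl3 <- cluster_unannotated(aln3, tagtab(c("AAA", "CCC"), c(5, 3)))
  expect_equal(length(cl3), 2L) # 38-nt gap exceeds 30
})

test_that("clusters recover the planted novel loci", {
  run <- default_run()
  man <- run$sim$manifest
  for (g in c("C", "H")) {
    cl <- run$discovery$clusters[[g]]
    for (i in seq_len(nrow(man$novel))) {
      hit <- any(as.character(GenomicRanges::strand(cl)) ==
                   man$novel$strand[i] &
                   GenomicRanges::start(cl) <= man$novel$mature_end[i] &
                   GenomicRanges::end(cl) >= man$novel$mature_start[i])
      # only expect recovery where the group has reads at the locus
      if (sum(run$libs$truth$counts[man$novel$id[i],
                                    run$libs$groups[[g]]] > 0) >= 1)
        expect_true(hit, info = paste(g, man$novel$id[i]))
    }
  }
})

test_that("candidate criteria flags behave as the rules dictate", {
  # plant a known-good novel hairpin in a small genome and call it
  d <- small_design()
  sim <- simulate_genome(d, 31L)
  man <- sim$manifest
  nv <- man$novel[1, ]
  aln <- aln_gr(nv$mature_start, nv$mature_end - nv$mature_start + 1L,
                nv$strand, nv$mature)
  cl <- cluster_unannotated(aln, tagtab(nv$mature, 10))
  cand <- call_candidates(cl, sim$genome, exons = NULL)
  expect_equal(nrow(cand), 1L)
  expect_true(cand$accepted)
  expect_lt(cand$mfe, -20)
  expect_true(cand$arm %in% c("5p", "3p"))
  expect_equal(cand$mature, nv$mature)
  # star pairs with the mature on the other side of the loop
  expect_false(is.na(cand$star))

  # a loose pseudo hairpin (MFE > -20) fails the stability criterion
  ps <- man$pseudo[man$pseudo$subtype == "loose", ][1, ]
  aln2 <- aln_gr(ps$mature_start, ps$mature_end - ps$mature_start + 1L,
                 ps$strand, ps$mature)
  cl2 <- cluster_unannotated(aln2, tagtab(ps$mature, 10))
  cand2 <- call_candidates(cl2, sim$genome, exons = NULL)
  expect_false(cand2$mfe_ok)
  expect_false(cand2$accepted)

  # a mature spanning the terminal loop fails the arm criterion:
  # centre the "mature" on the precursor midpoint
  mid <- floor((nv$start + nv$end) / 2)
  g <- as.character(sim$genome[[1]])
  loop_tag <- substr(g, mid - 10L, mid + 11L)
  aln3 <- aln_gr(mid - 10L, 22L, "+", loop_tag)
  cl3 <- cluster_unannotated(aln3, tagtab(loop_tag, 10))
  cand3 <- call_candidates(cl3, sim$genome, exons = NULL)
  expect_false(cand3$arm_ok[1] && cand3$accepted[1])

  # an exonic locus fails the locus criterion even with a good hairpin
  exon_here <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(nv$start - 50L, nv$end + 50L), strand = "+")
  exon_here$category <- "exon"
  cand4 <- call_candidates(cl, sim$genome, exons = exon_here)
  expect_false(cand4$locus_ok)
  expect_false(cand4$accepted)
  expect_true(cand4$mfe_ok) # other criteria unaffected by the exon flag
})

test_that("triplet features match the brute-force tally", {
  # all-unpaired homopolymer: single feature carries all the mass
  tf <- triplet_features("........." , sequence = "AAAAAAAAA")
  expect_equal(unname(tf[["A..."]]), 1)
  expect_equal(sum(tf), 1)
  expect_equal(attr(tf, "n_triplets"), 7L)
  # random folded hairpins match the per-position oracle and sum to L-2
  set.seed(77)
  for (t in 1:20) {
    s <- random_rna(sample(40:90, 1))
    f <- fold(s)
    tf <- triplet_features(f)
    orc <- oracle_triplets(f$sequence, f$structure)
    expect_equal(as.numeric(tf), unname(orc[names(tf)]), tolerance = 1e-12)
    expect_equal(sum(tf) * attr(tf, "n_triplets"), nchar(s) - 2,
                 tolerance = 1e-9)
  }
  expect_error(triplet_features("(((", sequence = "ACGU"), "lengths differ")
})

test_that("the classifier separates a separable set and inverts on label swap", {
  hs <- simulate_hairpin_set(20, 20, 41L)
  cl <- train_hairpin_classifier(hs)
  x <- t(vapply(hs$sequence, function(s)
    as.numeric(triplet_features(fold(s))), numeric(32)))
  colnames(x) <- cl$features
  sc <- predict(cl, x)
  acc <- mean((sc >= 0) == (hs$class == "real"))
  expect_gte(acc, 0.95) # near-perfect on its own training set
  # label swap: every verdict inverts
  hs2 <- hs
  hs2$class <- ifelse(hs$class == "real", "pseudo", "real")
  cl2 <- train_hairpin_classifier(hs2)
  sc2 <- predict(cl2, x)
  expect_true(all(sign(sc2) == -sign(sc) | sc == 0))
  # degenerate single-class training is refused
  expect_error(train_hairpin_classifier(hs[hs$class == "real", ]),
               "both classes")
})

test_that("held-out real/pseudo accuracy exceeds 80%", {
  cl <- default_run()$classifier
  held <- simulate_hairpin_set(50, 50, 43L)
  x <- t(vapply(held$sequence, function(s)
    as.numeric(triplet_features(fold(s))), numeric(32)))
  colnames(x) <- cl$features
  sc <- predict(cl, x)
  expect_gt(mean((sc >= 0) == (held$class == "real")), 0.8)
})

test_that("known-miRNA exclusion applies the <=2-mismatch same-length rule", {
  cand <- data.frame(id = c("a", "b", "c"),
                     mature = c("ACGTACGTACGTACGTACGTAC",
                                "ACGAACGAACGTACGTACGTAC",
                                "TTTTTTTTTTTTTTTTTTTTTT"),
                     stringsAsFactors = FALSE)
  catalog <- c(known = "ACGTACGTACGTACGTACGTAC")
  out <- exclude_known(cand, catalog)
  # exact match excluded; 2 mismatches excluded; unrelated retained
  expect_equal(out$id, "c")
  expect_equal(attr(out, "known")$id, c("a", "b"))
  # 3 mismatches are retained
  cand3 <- data.frame(id = "d", mature = "ACGAACGAACGAACGTACGTAC",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(exclude_known(cand3, catalog)), 1L)
  # U/T equivalence
  expect_equal(nrow(exclude_known(cand[1, ],
    c(k = "ACGUACGUACGUACGUACGUAC"))), 0L)
  # empty catalog passes through with a warning
  expect_warning(out2 <- exclude_known(cand, character(0)), "empty")
  expect_equal(nrow(out2), 3L)
})

test_that("replicate consistency keeps >=2-of-3 detections per group", {
  counts <- rbind(c(1, 2, 0, 1, 1, 1),   # detected twice in C: kept
                  c(3, 0, 0, 1, 1, 0),   # only C1: dropped for C
                  c(1, 1, 1, 0, 0, 0))   # never in H: not common
  colnames(counts) <- c("C1", "C2", "C3", "H1", "H2", "H3")
  rownames(counts) <- c("x", "y", "z")
  groups <- list(C = c("C1", "C2", "C3"), H = c("H1", "H2", "H3"))
  rc <- replicate_consistency(counts, groups)
  expect_true(rc["x", "kept_C"])
  expect_false(rc["y", "kept_C"])
  expect_true(rc["x", "common"])
  expect_false(rc["z", "common"])
  expect_error(replicate_consistency(counts, list(C = "C1", H = "H1")),
               "fewer than 2")
})

test_that("the funnel never grows and criteria flags gate acceptance", {
  run <- default_run()
  disc <- run$discovery
  n_acc <- sum(vapply(disc$accepted, nrow, integer(1)))
  expect_lte(nrow(disc$common), min(vapply(disc$accepted, nrow,
                                           integer(1))))
  expect_lte(nrow(disc$after_known), nrow(disc$common))
  expect_lte(nrow(disc$after_consistency), nrow(disc$after_known))
  expect_lte(nrow(disc$final), nrow(disc$after_consistency))
  for (g in names(disc$candidates)) {
    cand <- disc$candidates[[g]]
    expect_equal(cand$accepted,
                 cand$arm_ok & cand$mfe_ok & cand$geometry_ok &
                   cand$locus_ok)
  }
})
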