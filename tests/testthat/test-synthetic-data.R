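test_that("design validation rejects impossible parameters", {
  expect_error(simulation_design(n_replicates_per_group = 1), "replicates")
  expect_error(simulation_design(reads_per_library = 0), "positive")
  expect_error(simulation_design(length_mode = 30), "18..24")
  expect_error(simulation_design(novel_fold_change = 0), "positive")
})

test_that("identical seeds give byte-identical genomes, reads and files", {
  d <- small_design()
  a <- simulate_genome(d, 5L)
  b <- simulate_genome(d, 5L)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$manifest$known, b$manifest$known)
  expect_identical(a$manifest$novel, b$manifest$novel)
  la <- simulate_libraries(a$genome, a$manifest, d, 6L)
  lb <- simulate_libraries(b$genome, b$manifest, d, 6L)
  expect_identical(la$libraries, lb$libraries)
  expect_identical(la$truth$counts, lb$truth$counts)
  fa <- file.path(tempfile(), "a"); fb <- file.path(tempfile(), "b")
  simulate_libraries(a$genome, a$manifest, d, 6L, outdir = fa)
  simulate_libraries(b$genome, b$manifest, d, 6L, outdir = fb)
  for (lib in names(la$libraries))
    expect_identical(readLines(file.path(fa, paste0(lib, ".fastq"))),
                     readLines(file.path(fb, paste0(lib, ".fastq"))))
})

test_that("a design with zero novel miRNAs yields an empty novel table", {
  d <- small_design(n_novel = 0L)
  sim <- simulate_genome(d, 2L)
  expect_null(sim$manifest$novel)
})

test_that("an undersized genome errors with the deficit", {
  d <- small_design(genome_length = 2000L)
  expect_error(simulate_genome(d, 1L), "deficit")
})

test_that("planted loci hold their sequences and respect the manifest", {
  ss <- small_sim()
  g <- as.character(ss$sim$genome[[1]])
  man <- ss$sim$manifest
  for (tab in list(man$known, man$novel, man$pseudo)) {
    for (i in seq_len(nrow(tab))) {
      sub <- substr(g, tab$start[i], tab$end[i])
      if (tab$strand[i] == "-")
        sub <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(sub)))
      expect_equal(sub, tab$precursor[i], info = tab$id[i])
      expect_gte(nchar(tab$mature[i]), 18L)
      expect_lte(nchar(tab$mature[i]), 26L)
    }
  }
  # distinct loci never overlap
  all_loci <- rbind(man$known[, c("start", "end")],
                    man$novel[, c("start", "end")],
                    man$pseudo[, c("start", "end")],
                    man$decoy[, c("start", "end")],
                    man$ncrna[, c("start", "end")],
                    man$hotspot[, c("start", "end")])
  all_loci <- all_loci[order(all_loci$start), ]
  expect_true(all(diff(all_loci$start) > 0))
  expect_true(all(all_loci$start[-1] > all_loci$end[-nrow(all_loci)]))
  expect_true(all(all_loci$end <= man$genome_length))
})

test_that("planted novel precursors satisfy the three criteria when refolded", {
  ss <- small_sim()
  man <- ss$sim$manifest
  for (i in seq_len(nrow(man$novel))) {
    f <- fold(man$novel$precursor[i])
    expect_lt(f$mfe, -20)
    g <- hairpin_geometry(f)
    st <- g$stems[[g$main]]
    m1 <- man$novel$mature_offset1[i]; m2 <- man$novel$mature_offset2[i]
    on5 <- m1 >= st$arm5[1] && m2 <= st$arm5[2]
    on3 <- m1 >= st$arm3[1] && m2 <= st$arm3[2]
    expect_true(on5 || on3, info = man$novel$id[i])
    expect_lte(if (on5) st$max_bulge5 else st$max_bulge3, 4L)
  }
  # down-regulation invariant: C abundance below H abundance
  expect_true(all(man$novel$mean_rpm_C < man$novel$mean_rpm_H))
})

test_that("libraries have the designed size, adapter and truth counts", {
  ss <- small_sim()
  d <- ss$design
  tr <- ss$libs$truth
  for (lib in names(ss$libs$libraries)) {
    reads <- ss$libs$libraries[[lib]]$sequence
    expect_length(reads, d$reads_per_library)
    expect_equal(sum(tr$counts[, lib]), d$reads_per_library)
  }
  # every error-free read ends in a prefix of the adapter (after its
  # insert); spot-check by regenerating one library without errors
  d0 <- small_design(error_rate = 0)
  s0 <- simulate_genome(d0, 11L)
  l0 <- simulate_libraries(s0$genome, s0$manifest, d0, 12L)
  reads <- l0$libraries$C1$sequence
  full <- paste0(d0$adapter, d0$adapter)
  ok <- vapply(reads, function(r) {
    n <- nchar(r)
    any(vapply(0:(n - 1), function(k)
      substr(r, k + 1, n) == substr(full, 1, n - k), logical(1)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("replicate abundances within a group correlate strongly", {
  run <- default_run()
  cnt <- run$libs$truth$counts
  feat <- rownames(cnt)[!rownames(cnt) %in%
                          c("unmappable", "contaminant", "lowqual",
                            "ambiguous")]
  for (g in run$libs$groups) {
    for (i in 1:(length(g) - 1)) for (j in (i + 1):length(g)) {
      r <- cor(log1p(cnt[feat, g[i]]), log1p(cnt[feat, g[j]]))
      expect_gt(r, 0.9)
    }
  }
})

test_that("planted group fold change is recovered within sampling error", {
  d <- small_design(replicate_sdlog = 0, error_rate = 0)
  sim <- simulate_genome(d, 21L)
  # pin one novel miRNA at 100 RPM in C and 500 in H
  sim$manifest$novel$mean_rpm_C[1] <- 100
  sim$manifest$novel$mean_rpm_H[1] <- 500
  libs <- simulate_libraries(sim$genome, sim$manifest, d, 22L)
  id <- sim$manifest$novel$id[1]
  rpmC <- mean(libs$truth$rpm[id, libs$groups$C])
  rpmH <- mean(libs$truth$rpm[id, libs$groups$H])
  # binomial sampling: ~100 RPM at 4000 clean reads is ~0.4 reads/library,
  # so pool groups; expected counts ~1.2 (C) and ~6 (H) per group
  expect_gt(rpmH / rpmC, 1.5)
  expect_lt(abs(rpmH - 500) / 500, 1)
})

test_that("Ct tables carry the designed fold change exactly at zero noise", {
  t1 <- simulate_ct_table(5, 5, fold_change = 1, sd_ct = 0, seed = 1)
  r1 <- ddct(t1)
  expect_equal(r1$ddct, 0, tolerance = 1e-9)
  expect_equal(r1$fold_change, 1, tolerance = 1e-9)
  t2 <- simulate_ct_table(5, 5, fold_change = 0.5, sd_ct = 0, seed = 1)
  r2 <- ddct(t2)
  expect_equal(r2$ddct, 1, tolerance = 1e-9)
  expect_equal(r2$fold_change, 0.5, tolerance = 1e-9)
  expect_error(simulate_ct_table(5, 5, fold_change = -1), "positive")
})

test_that("hairpin training sets contain valid labelled classes", {
  hs <- simulate_hairpin_set(5, 5, 3)
  expect_equal(table(hs$class)[["real"]], 5L)
  expect_equal(table(hs$class)[["pseudo"]], 5L)
  for (s in hs$sequence[hs$class == "real"])
    expect_lt(fold(s)$mfe, -20)
})
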