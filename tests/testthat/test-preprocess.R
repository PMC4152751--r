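adapter <- "TGGAATTCTCGGGTGCCAAGG"

fq <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  list(sequence = seqs, quality = quals)
}

test_that("adapter-bearing reads are trimmed and kept", {
  insert <- "ACGTACGTACGTACGTAC" # 18-mer
  res <- clean_reads(fq(paste0(insert, adapter)), adapter)
  expect_equal(res$sequence, insert)
  expect_equal(res$summary$clean_reads, 1L)
})

test_that("inserts shorter than min_len are discarded as contaminants", {
  res <- clean_reads(fq(paste0("ACGT", adapter, "ACGTACGTACG")), adapter)
  expect_equal(length(res$sequence), 0L)
  expect_equal(res$summary$discarded_contaminant, 1L)
})

test_that("quality, ambiguity and length rules apply", {
  insert <- strrep("ACGT", 5) # 20-mer
  lowq <- paste0(strrep("I", 5), "#", strrep("I", nchar(insert) +
                                               nchar(adapter) - 6))
  res <- clean_reads(fq(
    c(paste0(insert, adapter),                       # clean
      paste0(insert, adapter),                       # low quality
      paste0(sub("A", "N", insert), adapter),        # ambiguous base
      paste0(strrep("ACGTACGT", 5), adapter)),       # 40-mer: too long
    quals = c(strrep("I", nchar(insert) + nchar(adapter)), lowq,
              strrep("I", nchar(insert) + nchar(adapter)),
              strrep("I", 40 + nchar(adapter)))), adapter)
  expect_equal(res$sequence, insert)
  expect_equal(res$summary$discarded_lowqual, 1L)
  expect_equal(res$summary$discarded_ambiguous, 1L)
  expect_equal(res$summary$discarded_length, 1L)
})

test_that("reads without adapter trigger a warning, not an error", {
  expect_warning(res <- clean_reads(fq(strrep("ACGT", 9)), adapter),
                 "adapter not found")
  expect_equal(res$summary$discarded_no_adapter, 1L)
})

test_that("adapter matching tolerates one mismatch at >= 6 nt overlap", {
  insert <- strrep("GA", 10)
  mut <- adapter
  substr(mut, 3, 3) <- "C" # one mismatch in a full-length occurrence
  res <- clean_reads(fq(paste0(insert, mut)), adapter)
  expect_equal(res$sequence, insert)
  # partial terminal adapter (8 nt) is also found
  res2 <- clean_reads(fq(paste0(insert, substr(adapter, 1, 8))), adapter)
  expect_equal(res2$sequence, insert)
})

test_that("read conservation holds on a simulated library", {
  ss <- small_sim()
  lib <- ss$libs$libraries[[1]]
  res <- clean_reads(lib, ss$design$adapter)
  s <- res$summary
  expect_equal(s$clean_reads + s$discarded_no_adapter +
                 s$discarded_contaminant + s$discarded_lowqual +
                 s$discarded_ambiguous + s$discarded_length,
               s$total_reads)
  expect_equal(s$total_reads, ss$design$reads_per_library)
})

test_that("cleaning matches the generator's bookkeeping", {
  ss <- small_sim()
  truth_clean <- ss$libs$truth$clean_reads
  for (lib in names(ss$libs$libraries)) {
    res <- clean_reads(ss$libs$libraries[[lib]], ss$design$adapter)
    expect_equal(res$summary$clean_reads, unname(truth_clean[lib]),
                 info = lib)
  }
})

test_that("trimming is idempotent on already-clean reads", {
  # a library of clean inserts whose 3' ends do not resemble the adapter
  # passes through cleaning untouched
  ss <- small_sim()
  res <- clean_reads(ss$libs$libraries[[2]], ss$design$adapter)
  resid <- mirnovel:::find_adapter(res$sequence, ss$design$adapter)
  pure <- res$sequence[is.na(resid)]
  again <- suppressWarnings(clean_reads(list(sequence = pure),
                                        ss$design$adapter))
  expect_identical(sort(again$sequence), sort(pure))
  # reads whose insert happens to end in adapter-like sequence are the
  # only ones partial-overlap matching may touch on a second pass
  again_all <- suppressWarnings(clean_reads(list(sequence = res$sequence),
                                            ss$design$adapter))
  lost <- setdiff(res$sequence, again_all$sequence)
  expect_true(all(!is.na(mirnovel:::find_adapter(lost,
                                                 ss$design$adapter))))
})

test_that("collapsing counts tags exactly and is order-invariant", {
  libs <- list(A = c("ACGT", "ACGT", "ACGT"), B = character(0))
  tab <- collapse_to_tags(libs)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$A, 3L)
  expect_equal(tab$B, 0L)

  ss <- small_sim()
  cleaned <- lapply(ss$libs$libraries[1:2], function(l)
    clean_reads(l, ss$design$adapter)$sequence)
  cleaned <- lapply(cleaned, head, 1000L)
  tab1 <- collapse_to_tags(cleaned)
  # column sums conserve clean reads
  for (l in names(cleaned))
    expect_equal(sum(tab1[[l]]), length(cleaned[[l]]))
  # equals the naive counting oracle
  orc <- oracle_tags(cleaned)
  expect_equal(tab1$sequence, orc$sequence)
  for (l in names(cleaned)) expect_equal(tab1[[l]], as.integer(orc[[l]]))
  # shuffled input gives the identical table
  set.seed(5)
  shuffled <- lapply(cleaned, sample)
  expect_identical(collapse_to_tags(shuffled), tab1)
})

test_that("length distribution reflects read lengths", {
  tab <- collapse_to_tags(list(L = rep(strrep("AC", 11), 4)))
  h <- length_distribution(tab, "L")
  expect_equal(unname(h[["22"]]), 4L)
  expect_equal(sum(h), 4L)
})

test_that("default simulations put the length mode in 21-23 nt", {
  run <- default_run()
  h <- length_distribution(run$tags, NULL)
  expect_true(as.integer(names(which.max(h))) %in% 21:23)
})

test_that("shared-tag statistics match set algebra", {
  tab <- collapse_to_tags(list(X = c("AAAA", "CCCC"), Y = c("AAAA", "GGGG")))
  st <- shared_tag_stats(tab, "X", "Y")
  expect_equal(st$pct_common_unique, 100 / 3)
  expect_equal(st$pct_common_total, 100 * 2 / 4)
  # identical libraries: 100 / 100
  tb2 <- collapse_to_tags(list(X = c("AAAA", "CCCC"), Y = c("AAAA", "CCCC")))
  st2 <- shared_tag_stats(tb2, "X", "Y")
  expect_equal(st2$pct_common_unique, 100)
  expect_equal(st2$pct_common_total, 100)
  # disjoint libraries: 0 / 0
  tb3 <- collapse_to_tags(list(X = "AAAA", Y = "CCCC"))
  st3 <- shared_tag_stats(tb3, "X", "Y")
  expect_equal(st3$pct_common_unique, 0)
  expect_equal(st3$pct_common_total, 0)
  # empty union is undefined
  tb4 <- collapse_to_tags(list(X = character(0), Y = character(0)))
  st4 <- shared_tag_stats(tb4, "X", "Y")
  expect_true(is.na(st4$pct_common_unique))
})
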