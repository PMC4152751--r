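#' Run the full novel-miRNA discovery funnel
#'
#' Executes the complete analysis on cleaned, collapsed and mapped data:
#' per-group candidate calling on unannotated clusters, intersection of
#' the groups' accepted candidates (common candidates), known-miRNA
#' exclusion, the detected-in->=2-of-3-replicates rule in every group,
#' and pseudo-precursor removal with the triplet-feature classifier.
#' Candidate expression is then RPM-normalised (0.01 pseudocount),
#' low-expression rows are dropped, and per-candidate fold changes and
#' Mann-Whitney tests are reported.
#'
#' @param tag_counts tag table from [collapse_to_tags()].
#' @param alignments tag alignment `GRanges` from [map_tags()].
#' @param categories per-tag annotation factor from [assign_category()].
#' @param genome genome as in [map_tags()].
#' @param features annotation `GRanges` (for the exon/locus criterion).
#' @param catalog known-miRNA catalog (see [exclude_known()]).
#' @param classifier a trained [train_hairpin_classifier()] model.
#' @param groups named list of library-name vectors.
#' @param clean_reads named vector of clean-read totals per library.
#' @param mfe_max,max_bulge,min_detect,max_gap stage parameters (see the
#'   stage functions).
#' @return a list with per-stage results: `clusters`, `candidates`
#'   (per-group tables with criteria flags), `accepted` (caller-accepted,
#'   both groups), `common`, `after_known`, `after_consistency`, `final`
#'   (classifier-passed novel miRNAs), `counts` (candidate x library),
#'   `expression` (RPM matrix after filtering) and `stats` (fold changes
#'   + Mann-Whitney p per final candidate).
#' @export
discover_novel_mirnas <- function(tag_counts, alignments, categories,
                                  genome, features, catalog, classifier,
                                  groups, clean_reads,
                                  mfe_max = -20, max_bulge = 4L,
                                  min_detect = 2L, max_gap = 30L) {
  unann_tags <- names(categories)[categories == "unannotated"]
  exons <- if (!is.null(features) && length(features))
    features[features$category == "exon"] else NULL

  call_group <- function(libs) {
    present <- rowSums(tag_counts[, libs, drop = FALSE]) > 0
    tags_g <- tag_counts$sequence[present]
    aln_g <- alignments[alignments$tag %in% intersect(unann_tags, tags_g)]
    cl <- cluster_unannotated(aln_g, tag_counts, max_gap = max_gap)
    cand <- call_candidates(cl, genome, exons, mfe_max = mfe_max,
                            max_bulge = max_bulge)
    if (nrow(cand)) {
      cand$mature_start <- cl$mature_start
      cand$mature_end <- cl$mature_end
    } else {
      cand$mature_start <- integer(0)
      cand$mature_end <- integer(0)
    }
    list(clusters = cl, candidates = cand)
  }
  per_group <- lapply(groups, call_group)
  accepted <- lapply(per_group, function(g)
    g$candidates[g$candidates$accepted, , drop = FALSE])

  # common candidates: accepted in every group at the same mature locus
  common <- accepted[[1]]
  if (length(accepted) > 1L && nrow(common)) {
    for (k in 2:length(accepted)) {
      other <- accepted[[k]]
      if (!nrow(other)) { common <- common[0, , drop = FALSE]; break }
      keep <- vapply(seq_len(nrow(common)), function(i) {
        any(other$strand == common$strand[i] &
              pmin(other$mature_end, common$mature_end[i]) >=
                pmax(other$mature_start, common$mature_start[i]))
      }, logical(1))
      common <- common[keep, , drop = FALSE]
    }
  }
  rownames(common) <- NULL
  if (nrow(common)) common$id <- sprintf("novel-cand-%03d",
                                         seq_len(nrow(common)))

  after_known <- exclude_known(common, catalog)

  counts <- candidate_counts(after_known, alignments, tag_counts)
  cons <- replicate_consistency(counts, groups, min_detect = min_detect)
  after_cons <- after_known[cons$common, , drop = FALSE]

  scored <- classify_pseudo(after_cons, classifier)
  final <- scored[scored$verdict == "real", , drop = FALSE]

  # expression of the final candidates
  stats <- NULL
  expr <- NULL
  if (nrow(final)) {
    cmat <- counts[final$id, , drop = FALSE]
    expr <- normalize_rpm(cmat, clean_reads[colnames(cmat)])
    expr <- filter_low_expression(expr, groups)
    if (nrow(expr)) {
      fc <- fold_change(expr, groups)
      pvals <- vapply(seq_len(nrow(expr)), function(i)
        mann_whitney(expr[i, groups[[1]]], expr[i, groups[[2]]])$p.value,
        numeric(1))
      stats <- cbind(fc, p.value = pvals)
    }
  }
  list(clusters = lapply(per_group, `[[`, "clusters"),
       candidates = lapply(per_group, `[[`, "candidates"),
       accepted = accepted, common = common, after_known = after_known,
       after_consistency = after_cons, final = final, counts = counts,
       expression = expr, stats = stats)
}

#' Simulate a study and run the whole pipeline against it
#'
#' Convenience wrapper used by the worked examples and the acceptance
#' checks: simulates the toy genome and libraries, cleans and collapses
#' the reads, maps and annotates the tags, trains the real/pseudo
#' classifier on an independently simulated hairpin set, and runs
#' [discover_novel_mirnas()].
#'
#' @param design a [simulation_design()].
#' @param seed integer master seed (sub-stages use `seed`, `seed + 1`,
#'   `seed + 2`).
#' @param n_train training hairpins per class for the classifier.
#' @return a list: `sim` (genome + manifest), `libs` (simulated
#'   libraries + truth), `summaries` (per-library cleaning summaries),
#'   `tags`, `mapping`, `categories`, `category_summary`, `classifier`
#'   and `discovery` (the [discover_novel_mirnas()] result).
#' @export
run_simulated_study <- function(design = simulation_design(), seed = 1L,
                                n_train = 30L) {
  seed <- as.integer(seed)
  sim <- simulate_genome(design, seed)
  libs <- simulate_libraries(sim$genome, sim$manifest, design, seed + 1L)

  cleaned <- lapply(libs$libraries, clean_reads, adapter = design$adapter)
  summaries <- do.call(rbind, lapply(cleaned, `[[`, "summary"))
  rownames(summaries) <- names(cleaned)
  tags <- collapse_to_tags(lapply(cleaned, `[[`, "sequence"))

  mapping <- map_tags(tags, sim$genome)
  features <- manifest_features(sim$manifest)
  categories <- assign_category(mapping$alignments, features)
  clean_totals <- setNames(summaries$clean_reads, rownames(summaries))
  catsum <- summarize_categories(categories, tags, clean_totals)

  train <- simulate_hairpin_set(n_train, n_train, seed + 2L)
  classifier <- train_hairpin_classifier(train)

  discovery <- discover_novel_mirnas(
    tags, mapping$alignments, categories, sim$genome, features,
    sim$manifest$catalog, classifier, libs$groups, clean_totals)

  list(sim = sim, libs = libs, summaries = summaries, tags = tags,
       mapping = mapping, categories = categories,
       category_summary = catsum, classifier = classifier,
       discovery = discovery)
}

#' Score a pipeline run against its truth manifest
#'
#' Computes recovery of the planted novel miRNAs through the full funnel
#' and the number of surviving planted pseudo hairpins.  A planted novel
#' miRNA is *eligible* when its true RPM is at least `min_rpm` in at
#' least `min_detect` replicates of every group; it is *recovered* when
#' a final candidate's mature locus overlaps its mature locus on the
#' same strand.
#'
#' @param run result of [run_simulated_study()].
#' @param min_rpm,min_detect eligibility rule (defaults 10 RPM, 2
#'   replicates).
#' @return a list: `n_eligible`, `n_recovered`, `recall`,
#'   `pseudo_survivors`, `eligible` (ids).
#' @export
score_against_truth <- function(run, min_rpm = 10, min_detect = 2L) {
  manifest <- run$sim$manifest
  truth_rpm <- run$libs$truth$rpm
  groups <- run$libs$groups
  novel <- manifest$novel
  final <- run$discovery$final
  eligible <- vapply(novel$id, function(id) {
    all(vapply(groups, function(libs)
      sum(truth_rpm[id, libs] >= min_rpm) >= min_detect, logical(1)))
  }, logical(1))
  hit <- vapply(which(eligible), function(i) {
    nrow(final) > 0 && any(
      final$strand == novel$strand[i] &
        pmin(final$mature_end, novel$mature_end[i]) >=
          pmax(final$mature_start, novel$mature_start[i]))
  }, logical(1))
  pseudo <- manifest$pseudo
  surv <- if (is.null(pseudo) || nrow(final) == 0) 0L else
    sum(vapply(seq_len(nrow(pseudo)), function(i)
      any(final$strand == pseudo$strand[i] &
            pmin(final$end, pseudo$end[i]) >=
              pmax(final$start, pseudo$start[i])), logical(1)))
  list(n_eligible = sum(eligible), n_recovered = sum(hit),
       recall = if (sum(eligible)) sum(hit) / sum(eligible) else NA_real_,
       pseudo_survivors = as.integer(surv),
       eligible = novel$id[eligible])
}
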