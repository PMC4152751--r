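#' Cluster unannotated tag alignments
#'
#' Groups alignments on the same strand whose gaps are at most `max_gap`
#' nt into clusters; each cluster's representative mature is its most
#' abundant tag (total count over libraries, ties broken towards the
#' leftmost then lexicographically smallest tag).
#'
#' @param alignments a `GRanges` of (unannotated) tag alignments with a
#'   `tag` metadata column.
#' @param tag_counts tag table from [collapse_to_tags()].
#' @param max_gap maximum gap in nt within a cluster (default 30).
#' @return a `GRanges` of clusters with metadata columns `n_tags`,
#'   `total_count`, `mature` (sequence), `mature_start`, `mature_end`.
#' @export
cluster_unannotated <- function(alignments, tag_counts, max_gap = 30L) {
  if (!length(alignments))
    return(GenomicRanges::GRanges())
  totals <- setNames(
    rowSums(tag_counts[, setdiff(names(tag_counts), "sequence"),
                       drop = FALSE]),
    tag_counts$sequence)
  cl <- GenomicRanges::reduce(alignments, min.gapwidth = max_gap + 1L,
                              ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(alignments, cl)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  # same-strand membership only
  same <- as.character(GenomicRanges::strand(alignments))[q] ==
    as.character(GenomicRanges::strand(cl))[s]
  q <- q[same]; s <- s[same]
  n_tags <- integer(length(cl))
  total <- numeric(length(cl))
  mature <- character(length(cl))
  mstart <- integer(length(cl))
  mend <- integer(length(cl))
  tagc <- totals[alignments$tag[q]]
  tagc[is.na(tagc)] <- 0
  for (i in seq_along(cl)) {
    sel <- q[s == i]
    cnt <- totals[alignments$tag[sel]]
    cnt[is.na(cnt)] <- 0
    n_tags[i] <- length(unique(alignments$tag[sel]))
    total[i] <- sum(cnt)
    ord <- order(-cnt, GenomicRanges::start(alignments)[sel],
                 alignments$tag[sel])
    top <- sel[ord[1]]
    mature[i] <- alignments$tag[top]
    mstart[i] <- GenomicRanges::start(alignments)[top]
    mend[i] <- GenomicRanges::end(alignments)[top]
  }
  cl$n_tags <- n_tags
  cl$total_count <- total
  cl$mature <- mature
  cl$mature_start <- mstart
  cl$mature_end <- mend
  cl
}

#' Call hairpin precursor candidates from unannotated clusters
#'
#' The MIREAP-style stage.  For each cluster, two genomic windows are
#' excised around the mature tag - extending `ext_short` nt on one side
#' and `ext_long` nt on the other, in both orientations - folded with
#' [fold()], and scored against the three precursor criteria:
#' * `arm_ok`: the mature lies wholly within one arm of the main stem
#'   (no overlap with the terminal loop) and is 18-26 nt;
#' * `geometry_ok`: no unpaired run longer than `max_bulge` nt within the
#'   mature-bearing arm (no large internal loops or bulges);
#' * `mfe_ok`: precursor MFE strictly below `mfe_max` kcal/mol;
#' * `locus_ok`: the mature locus does not overlap an exon (intronic or
#'   intergenic loci only).
#' The better-scoring window is kept; the precursor reported is the main
#' stem span, refolded in isolation.  Windows clipped at the genome edge
#' are truncated with a warning.
#'
#' @param clusters cluster `GRanges` from [cluster_unannotated()].
#' @param genome genome as in [map_tags()].
#' @param exons `GRanges` of exon features (e.g. subset of
#'   [manifest_features()]), or `NULL` when no exon annotation exists.
#' @param mfe_max MFE acceptance threshold in kcal/mol (default -20).
#' @param max_bulge largest tolerated unpaired run in the mature arm
#'   (default 4 nt).
#' @param ext_short,ext_long window extensions in nt (default 20/100).
#' @return a data.frame of candidates, one row per cluster: locus
#'   (`chrom`, `start`, `end`, `strand`), `precursor`, `structure`,
#'   `mfe`, `mature`, `arm`, `star`, the four criteria flags and
#'   `accepted` (all flags true).
#' @export
call_candidates <- function(clusters, genome, exons = NULL, mfe_max = -20,
                            max_bulge = 4L, ext_short = 20L,
                            ext_long = 100L) {
  genome <- load_genome(genome)
  gseq <- as.character(genome[[1]])
  glen <- nchar(gseq)
  chrom <- names(genome)[1]
  if (!length(clusters)) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), precursor = character(0),
                      structure = character(0), mfe = numeric(0),
                      mature = character(0), arm = character(0),
                      star = character(0), arm_ok = logical(0),
                      mfe_ok = logical(0), geometry_ok = logical(0),
                      locus_ok = logical(0), accepted = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- vector("list", length(clusters))
  for (i in seq_along(clusters)) {
    m1 <- clusters$mature_start[i]
    m2 <- clusters$mature_end[i]
    strand <- as.character(GenomicRanges::strand(clusters))[i]
    mature <- clusters$mature[i]
    wins <- list(c(m1 - ext_short, m2 + ext_long),
                 c(m1 - ext_long, m2 + ext_short))
    best <- NULL
    for (w in wins) {
      ws <- max(1L, w[1]); we <- min(glen, w[2])
      if (ws != w[1] || we != w[2])
        warning("candidate window truncated at genome bounds near ",
                m1, "-", m2)
      ev <- evaluate_window(gseq, ws, we, strand, m1, m2, mfe_max, max_bulge)
      if (is.null(best) ||
          (ev$n_flags > best$n_flags) ||
          (ev$n_flags == best$n_flags && ev$mfe < best$mfe))
        best <- ev
    }
    mat_len_ok <- nchar(mature) >= 18L && nchar(mature) <= 26L
    arm_ok <- best$arm_ok && mat_len_ok
    locus_ok <- TRUE
    if (!is.null(exons) && length(exons)) {
      mgr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(m1, m2))
      locus_ok <- !any(IRanges::overlapsAny(
        mgr, exons[exons$category == "exon"], ignore.strand = TRUE))
    }
    res[[i]] <- data.frame(
      id = sprintf("cand-%04d", i), chrom = chrom,
      start = best$prec_start, end = best$prec_end, strand = strand,
      precursor = best$precursor, structure = best$structure,
      mfe = best$mfe, mature = mature, arm = best$arm, star = best$star,
      arm_ok = arm_ok, mfe_ok = best$mfe_ok, geometry_ok = best$geometry_ok,
      locus_ok = locus_ok, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$accepted <- out$arm_ok & out$mfe_ok & out$geometry_ok & out$locus_ok
  rownames(out) <- NULL
  out
}

# fold one genomic window and score the hairpin criteria for a mature at
# genomic positions m1..m2; returns precursor (main stem span) metrics
evaluate_window <- function(gseq, ws, we, strand, m1, m2, mfe_max,
                            max_bulge) {
  seq <- substr(gseq, ws, we)
  if (strand == "-") seq <- revcomp_chr(seq)
  # mature position within the window, in fold orientation
  if (strand == "+") {
    f1 <- m1 - ws + 1L; f2 <- m2 - ws + 1L
  } else {
    f1 <- we - m2 + 1L; f2 <- we - m1 + 1L
  }
  fail <- list(arm_ok = FALSE, geometry_ok = FALSE, mfe_ok = FALSE,
               n_flags = 0L, mfe = 0, precursor = seq, structure = NULL,
               arm = NA_character_, star = NA_character_,
               prec_start = ws, prec_end = we)
  f <- fold(seq)
  g <- hairpin_geometry(f)
  if (g$n_stems == 0L) {
    fail$structure <- f$structure
    return(fail)
  }
  # stem containing the mature, else the main stem
  span_has <- vapply(g$stems, function(s)
    f1 >= s$outer[1] && f2 <= s$outer[2], logical(1))
  si <- if (any(span_has)) {
    cand <- which(span_has)
    cand[which.max(vapply(g$stems[cand], `[[`, integer(1), "n_pairs"))]
  } else g$main
  st <- g$stems[[si]]

  # precursor span: mature plus its pairing partners (the star side) with
  # a small pad, rather than the whole stem span, so that flanking
  # sequence caught in the window fold does not dilute the arm geometry
  wpt <- pair_table(f$structure)
  partners <- wpt[f1:min(f2, length(wpt))]
  partners <- partners[partners > 0]
  if (length(partners) >= 2L) {
    p1 <- max(1L, min(f1, min(partners)) - 3L)
    p2 <- min(nchar(seq), max(f2, max(partners)) + 3L)
  } else {
    p1 <- st$outer[1]; p2 <- st$outer[2]
  }
  prec <- substr(seq, p1, p2)
  pf <- fold(prec)
  pg <- hairpin_geometry(pf)
  # genomic coordinates of the precursor span
  if (strand == "+") {
    gs <- ws + p1 - 1L; ge <- ws + p2 - 1L
  } else {
    gs <- we - p2 + 1L; ge <- we - p1 + 1L
  }
  out <- list(mfe = pf$mfe, precursor = prec, structure = pf$structure,
              prec_start = gs, prec_end = ge,
              arm = NA_character_, star = NA_character_)
  pm1 <- f1 - p1 + 1L; pm2 <- f2 - p1 + 1L # mature within precursor
  out$mfe_ok <- pf$mfe < mfe_max
  out$arm_ok <- FALSE
  out$geometry_ok <- FALSE
  if (pg$n_stems > 0L && pm1 >= 1L && pm2 <= nchar(prec)) {
    has <- vapply(pg$stems, function(s)
      pm1 >= s$outer[1] && pm2 <= s$outer[2], logical(1))
    pi <- if (any(has)) {
      cand <- which(has)
      cand[which.max(vapply(pg$stems[cand], `[[`, integer(1), "n_pairs"))]
    } else pg$main
    ps <- pg$stems[[pi]]
    on5 <- pm1 >= ps$arm5[1] && pm2 <= ps$arm5[2]
    on3 <- pm1 >= ps$arm3[1] && pm2 <= ps$arm3[2]
    if (on5 || on3) {
      out$arm_ok <- TRUE
      out$arm <- if (on5) "5p" else "3p"
      out$geometry_ok <- (if (on5) ps$max_bulge5 else ps$max_bulge3) <=
        max_bulge
      # star: region pairing with the mature ends
      pt <- pair_table(pf$structure)
      prt <- pt[pm1:pm2]
      prt <- prt[prt > 0]
      if (length(prt) >= 2L)
        out$star <- substr(prec, min(prt), max(prt))
    }
  }
  out$n_flags <- sum(out$arm_ok, out$geometry_ok, out$mfe_ok)
  out
}

#' Triplet structure-sequence features of a folded precursor
#'
#' For every interior position of the precursor, the local structure
#' triplet is the paired/unpaired pattern of the three consecutive
#' positions (brackets normalised so each position is either paired, "(",
#' or unpaired, "."), combined with the middle nucleotide: 8 patterns x 4
#' bases = 32 features, normalised to frequencies over the L-2 interior
#' triplets.
#'
#' @param fold a `hairpin_fold` object, or a dot-bracket string (then
#'   `sequence` is required).
#' @param sequence nucleotide string (defaults to the fold's sequence).
#' @return named numeric vector of 32 frequencies summing to 1, with the
#'   raw triplet count total (L-2) as attribute `n_triplets`.
#' @export
triplet_features <- function(fold, sequence = NULL) {
  if (inherits(fold, "hairpin_fold")) {
    db <- fold$structure
    if (is.null(sequence)) sequence <- fold$sequence
  } else {
    db <- as.character(fold)
    if (is.null(sequence)) stop("'sequence' required with a bare structure")
  }
  rna <- chartr("T", "U", toupper(sequence))
  if (nchar(rna) != nchar(db))
    stop("sequence and structure lengths differ")
  if (nchar(rna) < 3L) stop("sequence too short for triplet features")
  s <- chartr("()", "((", db)
  sch <- strsplit(s, "", fixed = TRUE)[[1]]
  bch <- strsplit(rna, "", fixed = TRUE)[[1]]
  if (any(!sch %in% c(".", "(")))
    stop("structure may only contain '.', '(' and ')'")
  pats <- c("...", "..(", ".(.", ".((", "(..", "(.(", "((.", "(((")
  feats <- as.vector(outer(pats, c("A", "C", "G", "U"),
                           function(p, b) paste0(b, p)))
  n <- length(sch)
  idx <- 2:(n - 1)
  trip <- paste0(bch[idx], sch[idx - 1], sch[idx], sch[idx + 1])
  cnt <- table(factor(trip, levels = feats))
  out <- as.numeric(cnt) / (n - 2)
  names(out) <- feats
  attr(out, "n_triplets") <- n - 2L
  out
}

#' Train the maximum-margin real/pseudo precursor classifier
#'
#' Fits a linear support vector machine (unit cost) on triplet feature
#' vectors of labelled real and pseudo hairpins.  Features are
#' standardised by training-set statistics inside the function;
#' zero-variance features are left unscaled.  The decision score is
#' oriented so that positive margins mean "real".
#'
#' @param hairpins a data.frame with `class` ("real"/"pseudo") and
#'   `sequence` columns (e.g. from [simulate_hairpin_set()]), or a
#'   precomputed feature matrix (then `labels` is required).
#' @param labels character/factor of "real"/"pseudo" when `hairpins` is a
#'   matrix.
#' @return an object of class `hairpin_classifier`.
#' @export
train_hairpin_classifier <- function(hairpins, labels = NULL) {
  if (is.data.frame(hairpins) && !is.null(hairpins$sequence)) {
    labels <- hairpins$class
    x <- t(vapply(hairpins$sequence,
                  function(s) as.numeric(triplet_features(fold(s))),
                  numeric(32)))
    colnames(x) <- names(triplet_features(fold(hairpins$sequence[1])))
  } else {
    x <- as.matrix(hairpins)
    if (is.null(labels)) stop("'labels' required with a feature matrix")
  }
  y <- factor(as.character(labels), levels = c("pseudo", "real"))
  if (any(is.na(y))) stop("labels must be 'real' or 'pseudo'")
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  model <- e1071::svm(xs, y, kernel = "linear", cost = 1, scale = FALSE)
  dv <- attr(predict(model, xs, decision.values = TRUE), "decision.values")
  flip <- if (mean(dv[y == "real", 1]) >= mean(dv[y == "pseudo", 1])) 1 else -1
  structure(list(model = model, center = ctr, scale = scl, flip = flip,
                 features = colnames(x)),
            class = "hairpin_classifier")
}

#' @export
predict.hairpin_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  x <- x[, object$features, drop = FALSE]
  xs <- scale(x, object$center, object$scale)
  dv <- attr(predict(object$model, xs, decision.values = TRUE),
             "decision.values")
  score <- object$flip * dv[, 1]
  unname(score)
}

#' Score candidates with the real/pseudo classifier
#'
#' @param candidates candidate table from [call_candidates()].
#' @param classifier a `hairpin_classifier`.
#' @return the candidate table with `classifier_score` and `verdict`
#'   ("real" iff score >= 0) columns added.
#' @export
classify_pseudo <- function(candidates, classifier) {
  stopifnot(inherits(classifier, "hairpin_classifier"))
  if (nrow(candidates) == 0L) {
    candidates$classifier_score <- numeric(0)
    candidates$verdict <- character(0)
    return(candidates)
  }
  x <- t(vapply(candidates$precursor,
                function(s) as.numeric(triplet_features(fold(s))),
                numeric(32)))
  colnames(x) <- classifier$features
  score <- predict(classifier, x)
  candidates$classifier_score <- score
  candidates$verdict <- ifelse(score >= 0, "real", "pseudo")
  candidates
}

#' Exclude candidates matching the known-miRNA catalog
#'
#' A candidate is removed when its mature matches a catalog mature of
#' identical length with at most `max_mismatch` substitutions.
#'
#' @param candidates candidate table with a `mature` column.
#' @param catalog known matures: character vector, `DNAStringSet`/
#'   `RNAStringSet`, or FASTA path.  U and T are equivalent.
#' @param max_mismatch mismatch tolerance (default 2).
#' @return the candidate table with matching rows removed; the removed
#'   rows are attached as attribute `"known"`.
#' @export
exclude_known <- function(candidates, catalog, max_mismatch = 2L) {
  cat <- if (is.character(catalog) && length(catalog) == 1L &&
             file.exists(catalog))
    as.character(Biostrings::readBStringSet(catalog)) else
      as.character(catalog)
  cat <- chartr("U", "T", toupper(cat))
  if (!length(cat)) {
    warning("empty known-miRNA catalog; no candidates excluded")
    attr(candidates, "known") <- candidates[0, , drop = FALSE]
    return(candidates)
  }
  hit <- vapply(chartr("U", "T", toupper(candidates$mature)), function(m) {
    same <- cat[nchar(cat) == nchar(m)]
    if (!length(same)) return(FALSE)
    mv <- utf8ToInt(m)
    any(vapply(same, function(s)
      sum(utf8ToInt(s) != mv) <= max_mismatch, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  out <- candidates[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "known") <- candidates[hit, , drop = FALSE]
  out
}

#' Replicate-consistency filter
#'
#' A candidate counts as detected in a library when it has at least one
#' mapped mature read there; it is kept for a group when detected in at
#' least `min_detect` of the group's replicates.  The cross-group common
#' set is the intersection (kept in every group).
#'
#' @param counts candidate x library count matrix (see
#'   [candidate_counts()]).
#' @param groups named list of library-name vectors, e.g.
#'   `list(C = c("C1","C2","C3"), H = c("H1","H2","H3"))`.
#' @param min_detect minimum replicates with detection (default 2).
#' @return a data.frame with one logical `kept_<group>` column per group
#'   and `common` (kept in all groups), rownames as in `counts`.
#' @export
replicate_consistency <- function(counts, groups, min_detect = 2L) {
  counts <- as.matrix(counts)
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2L)
      stop("group '", g, "' has fewer than 2 replicates")
    if (!all(groups[[g]] %in% colnames(counts)))
      stop("group '", g, "' names libraries absent from counts")
  }
  out <- data.frame(row.names = rownames(counts))
  for (g in names(groups)) {
    det <- rowSums(counts[, groups[[g]], drop = FALSE] >= 1)
    out[[paste0("kept_", g)]] <- det >= min_detect
  }
  out$common <- Reduce(`&`, out[paste0("kept_", names(groups))])
  out
}

#' Per-library mature read counts of candidates
#'
#' Sums counts of all tags whose alignments fall on the candidate strand
#' with a start within `slop` nt of the candidate mature locus (capturing
#' trimmed length variants of the mature).
#'
#' @param candidates candidate table from [call_candidates()] (uses
#'   `mature` plus the cluster mature locus columns carried in `...`);
#'   needs `mature_start`, `mature_end`, `strand` columns - these are
#'   joined in by [discover_novel_mirnas()] from the cluster table.
#' @param alignments tag alignment `GRanges`.
#' @param tag_counts tag table from [collapse_to_tags()].
#' @param slop start tolerance in nt (default 3).
#' @return candidate x library integer matrix.
#' @export
candidate_counts <- function(candidates, alignments, tag_counts,
                             slop = 3L) {
  libs <- setdiff(names(tag_counts), "sequence")
  m <- matrix(0L, nrow(candidates), length(libs),
              dimnames = list(candidates$id, libs))
  if (!nrow(candidates) || !length(alignments)) return(m)
  astart <- GenomicRanges::start(alignments)
  aend <- GenomicRanges::end(alignments)
  astrand <- as.character(GenomicRanges::strand(alignments))
  cnt_idx <- match(alignments$tag, tag_counts$sequence)
  for (i in seq_len(nrow(candidates))) {
    near <- which(astrand == candidates$strand[i] &
                    abs(astart - candidates$mature_start[i]) <= slop &
                    aend <= candidates$mature_end[i] + slop &
                    !is.na(cnt_idx))
    if (!length(near)) next
    rows <- unique(cnt_idx[near])
    for (l in libs) m[i, l] <- sum(tag_counts[[l]][rows])
  }
  m
}
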