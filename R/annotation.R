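#' Map unique tags to a genome by exact matching
#'
#' Finds all exact (0-mismatch) occurrences of each tag on both strands
#' of the genome.  A hit on the minus strand means the tag equals the
#' reverse complement of the genomic substring at the locus.
#'
#' @param tags character vector of tag sequences, or a tag table from
#'   [collapse_to_tags()].
#' @param genome a [Biostrings::DNAStringSet] (first sequence used), a
#'   [Biostrings::DNAString], or a FASTA path.
#' @return a list with `alignments` (a [GenomicRanges::GRanges] with
#'   metadata columns `tag` and `n_hits`, the tag's total hit count over
#'   both strands) and `unmapped` (character vector of unplaced tags).
#' @export
map_tags <- function(tags, genome) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- toupper(as.character(tags))
  genome <- load_genome(genome)
  subject <- genome[[1]]
  chrom <- names(genome)[1]
  glen <- length(subject)

  hit_frame <- function(seqs, strand) {
    out <- list()
    for (w in unique(nchar(seqs))) {
      sel <- which(nchar(seqs) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[sel]))
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      n_per <- lengths(starts)
      if (sum(n_per) == 0) next
      idx <- rep(sel, n_per)
      st <- unlist(starts, use.names = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(tag_idx = idx, start = st, width = w,
                   strand = strand, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  uniq <- unique(tags)
  plus <- hit_frame(uniq, "+")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(uniq)))
  minus <- hit_frame(rc, "-")
  hits <- rbind(plus, minus)
  if (is.null(hits)) {
    gr <- GenomicRanges::GRanges()
    return(list(alignments = gr, unmapped = uniq))
  }
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(hits$start, width = hits$width),
    strand = hits$strand)
  gr$tag <- uniq[hits$tag_idx]
  nh <- table(hits$tag_idx)
  gr$n_hits <- as.integer(nh[as.character(hits$tag_idx)])
  list(alignments = gr, unmapped = setdiff(uniq, gr$tag))
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (is(genome, "DNAString")) {
    genome <- Biostrings::DNAStringSet(genome)
    names(genome) <- "chr1"
  }
  stopifnot(is(genome, "DNAStringSet"), length(genome) >= 1L)
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  genome
}

.category_levels <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                      "repeat", "exon_sense", "exon_antisense",
                      "intron_sense", "intron_antisense", "unannotated")

#' Annotation category levels in priority order
#'
#' The fixed hierarchy used by [assign_category()]: miRNA > rRNA > tRNA >
#' snRNA > snoRNA > scRNA > repeat > exon (sense, antisense) > intron
#' (sense, antisense) > unannotated.
#'
#' @return character vector of category labels.
#' @export
category_levels <- function() .category_levels

#' Assign each mapped tag to one annotation category
#'
#' A tag alignment overlaps a feature when at least `min_frac` of the tag
#' length lies inside the feature interval.  Exon and intron overlaps are
#' split by strand into sense/antisense.  Each *tag* receives the single
#' highest-priority category over all its alignments and feature hits
#' (so multi-hit tags are counted once, and categories partition tags).
#'
#' @param alignments a `GRanges` of tag alignments from [map_tags()]
#'   (metadata column `tag`).
#' @param features a `GRanges` with a `category` metadata column using
#'   labels miRNA/rRNA/tRNA/snRNA/snoRNA/scRNA/repeat/exon/intron, e.g.
#'   from [manifest_features()] or [read_feature_gff()].
#' @param min_frac minimum overlap as a fraction of tag length.
#' @return named factor: category per unique tag, levels
#'   [category_levels()]; tags with no qualifying feature overlap are
#'   "unannotated".
#' @export
assign_category <- function(alignments, features, min_frac = 0.5) {
  base_ok <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
               "repeat", "exon", "intron")
  if (is.null(features$category))
    stop("'features' needs a 'category' metadata column")
  bad <- setdiff(unique(as.character(features$category)), base_ok)
  if (length(bad))
    stop("unknown feature label(s) in annotation: ",
         paste(bad, collapse = ", "))
  tags <- unique(alignments$tag)
  rank <- setNames(seq_along(.category_levels), .category_levels)
  best <- setNames(rep(rank[["unannotated"]], length(tags)), tags)
  if (length(alignments) && length(features)) {
    ov <- GenomicRanges::findOverlaps(alignments, features,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(alignments)[q],
        GenomicRanges::ranges(features)[s]))
      okov <- w >= min_frac * GenomicRanges::width(alignments)[q]
      q <- q[okov]; s <- s[okov]
      if (length(q)) {
        cat <- as.character(features$category)[s]
        sense <- as.character(GenomicRanges::strand(alignments))[q] ==
          as.character(GenomicRanges::strand(features))[s]
        ei <- cat %in% c("exon", "intron")
        cat[ei] <- paste0(cat[ei], ifelse(sense[ei], "_sense", "_antisense"))
        r <- rank[cat]
        tg <- alignments$tag[q]
        agg <- tapply(r, tg, min)
        best[names(agg)] <- pmin(best[names(agg)], agg)
      }
    }
  }
  out <- factor(.category_levels[best], levels = .category_levels)
  names(out) <- tags
  out
}

#' Read an annotation interval file (GFF3 or BED)
#'
#' Imports feature intervals and exposes the feature class as the
#' `category` column ("type" for GFF, "name" for BED).  Unknown labels
#' are rejected by [assign_category()] downstream.
#'
#' @param path GFF3 or BED file.
#' @return a `GRanges` with a `category` metadata column.
#' @export
read_feature_gff <- function(path) {
  gr <- rtracklayer::import(path)
  cat <- if (!is.null(gr$type)) as.character(gr$type) else
    if (!is.null(gr$name)) as.character(gr$name) else
      stop("annotation file has neither 'type' nor 'name' field: ", path)
  gr$category <- cat
  gr
}

#' Per-category read-count summary of annotated libraries
#'
#' Builds the per-library category table: read counts for every category
#' in [category_levels()] plus an `unmapped` row, and the unannotated
#' percentage of clean reads rounded to 2 decimals.  The table can be
#' built either from tag-level annotation (factor + tag counts) or fed
#' directly with a pre-tabulated category count matrix (rows = any subset
#' of categories, columns = libraries).
#'
#' @param categories a named factor from [assign_category()], or a
#'   numeric category x library count matrix.
#' @param tag_counts tag table from [collapse_to_tags()] (required in the
#'   factor case; its non-`sequence` columns are the libraries).  Tags
#'   absent from `categories` are counted as unmapped.
#' @param clean_reads named vector of clean-read totals per library.
#' @return a list with `counts` (category x library matrix) and
#'   `unannotated_pct` (named vector, 2 decimals; `NA` where clean reads
#'   are 0).
#' @export
summarize_categories <- function(categories, tag_counts = NULL,
                                 clean_reads = NULL) {
  if (is.matrix(categories) || is.data.frame(categories)) {
    counts <- as.matrix(categories)
    if (is.null(clean_reads)) stop("clean_reads required with matrix input")
  } else {
    stopifnot(is.factor(categories), !is.null(tag_counts))
    libs <- setdiff(names(tag_counts), "sequence")
    if (is.null(clean_reads))
      clean_reads <- setNames(vapply(libs, function(l)
        sum(tag_counts[[l]]), numeric(1)), libs)
    rows <- c(.category_levels, "unmapped")
    counts <- matrix(0, length(rows), length(libs),
                     dimnames = list(rows, libs))
    cat_of <- setNames(as.character(categories), names(categories))
    tagcat <- cat_of[tag_counts$sequence]
    tagcat[is.na(tagcat)] <- "unmapped"
    for (l in libs) {
      agg <- tapply(tag_counts[[l]], tagcat, sum)
      counts[names(agg), l] <- agg
    }
  }
  if (!"unannotated" %in% rownames(counts))
    stop("category counts must include an 'unannotated' row")
  clean <- clean_reads[colnames(counts)]
  pct <- ifelse(clean > 0,
                round(100 * counts["unannotated", ] / clean, 2), NA_real_)
  list(counts = counts, unannotated_pct = setNames(as.numeric(pct),
                                                   colnames(counts)))
}
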