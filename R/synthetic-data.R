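#' Design of a simulated serum small-RNA experiment
#'
#' Collects the tunable parameters of the synthetic-data generator: a
#' two-group (cervical-cancer "C" vs healthy-control "H") pooled-serum
#' design with replicated libraries, a single-chromosome toy genome
#' carrying planted known/novel miRNA precursors, criteria-passing pseudo
#' hairpins, other ncRNA loci and intergenic degradation hotspots, plus
#' 3'-adapter ligation and the usual read-level nuisance classes
#' (adapter dimers, low-quality reads, ambiguous bases).
#'
#' `category_fractions` gives the expected composition of *clean* reads
#' and is normalised internally; `contaminant_fraction`,
#' `lowqual_fraction` and `ambiguous_fraction` are fractions of *total*
#' reads.  Novel (and decoy) miRNAs are down-regulated in the C group by
#' `novel_fold_change` (C/H ratio of mean RPM).
#'
#' @param n_replicates_per_group replicate libraries per group (>= 2).
#' @param reads_per_library total raw reads per library.
#' @param read_length raw read length in nt (inserts shorter than this
#'   read into the 3' adapter).
#' @param length_mode modal mature length in nt (18-24).
#' @param genome_length toy genome size in nt.
#' @param n_known,n_novel,n_pseudo_stable,n_pseudo_loose,n_decoy,n_hotspots
#'   numbers of planted features.  "Stable" pseudo hairpins satisfy the
#'   hairpin criteria but have pseudo-like triplet composition; "loose"
#'   ones fail the -20 kcal/mol stability criterion.  The decoy is an
#'   unannotated hairpin whose mature sequence is in the known catalog.
#' @param adapter 3' adapter sequence.
#' @param novel_fold_change true C/H ratio of novel-miRNA abundance (< 0.5
#'   emulates the observed > 2-fold down-regulation in the cancer group).
#' @param replicate_sdlog per-replicate log-normal abundance dispersion.
#' @param feature_sdlog between-feature log-normal abundance dispersion.
#' @param error_rate per-read uniform substitution probability.
#' @param category_fractions named non-negative vector over the clean read
#'   categories (see default).
#' @param contaminant_fraction,lowqual_fraction,ambiguous_fraction
#'   fractions of total reads that are adapter dimers, carry a base below
#'   Phred 20, or contain an N.
#' @return an object of class `sim_design`.
#' @export
simulation_design <- function(n_replicates_per_group = 3L,
                              reads_per_library = 20000L,
                              read_length = 36L,
                              length_mode = 22L,
                              genome_length = 100000L,
                              n_known = 8L,
                              n_novel = 6L,
                              n_pseudo_stable = 5L,
                              n_pseudo_loose = 5L,
                              n_decoy = 1L,
                              n_hotspots = 40L,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              novel_fold_change = 0.25,
                              replicate_sdlog = 0.3,
                              feature_sdlog = 1.0,
                              error_rate = 0.001,
                              category_fractions = c(
                                miRNA = 0.33, rRNA = 0.02, tRNA = 0.012,
                                snRNA = 0.006, snoRNA = 0.003, scRNA = 0.003,
                                repeat_ = 0.012, exon = 0.006, intron = 0.006,
                                hotspot = 0.06, novel = 0.012, pseudo = 0.008,
                                decoy = 0.002, unmappable = 0.43),
                              contaminant_fraction = 0.015,
                              lowqual_fraction = 0.02,
                              ambiguous_fraction = 0.005) {
  if (n_replicates_per_group < 2L)
    stop("n_replicates_per_group must be >= 2")
  if (reads_per_library <= 0L) stop("reads_per_library must be positive")
  if (length_mode < 18L || length_mode > 24L)
    stop("length_mode must lie in 18..24 nt")
  if (!nzchar(adapter) || grepl("[^ACGT]", adapter))
    stop("adapter must be a non-empty ACGT string")
  if (novel_fold_change <= 0) stop("novel_fold_change must be positive")
  need <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat_",
            "exon", "intron", "hotspot", "novel", "pseudo", "decoy",
            "unmappable")
  if (!all(need %in% names(category_fractions)) ||
      any(category_fractions < 0))
    stop("category_fractions must be a non-negative vector over: ",
         paste(need, collapse = ", "))
  category_fractions <- category_fractions[need] / sum(category_fractions[need])
  special <- contaminant_fraction + lowqual_fraction + ambiguous_fraction
  if (special >= 0.5) stop("nuisance read fractions are implausibly large")
  d <- list(n_replicates_per_group = as.integer(n_replicates_per_group),
            reads_per_library = as.integer(reads_per_library),
            read_length = as.integer(read_length),
            length_mode = as.integer(length_mode),
            genome_length = as.integer(genome_length),
            n_known = as.integer(n_known), n_novel = as.integer(n_novel),
            n_pseudo_stable = as.integer(n_pseudo_stable),
            n_pseudo_loose = as.integer(n_pseudo_loose),
            n_decoy = as.integer(n_decoy),
            n_hotspots = as.integer(n_hotspots),
            adapter = adapter,
            novel_fold_change = novel_fold_change,
            replicate_sdlog = replicate_sdlog,
            feature_sdlog = feature_sdlog,
            error_rate = error_rate,
            category_fractions = category_fractions,
            contaminant_fraction = contaminant_fraction,
            lowqual_fraction = lowqual_fraction,
            ambiguous_fraction = ambiguous_fraction)
  d$fraction_unannotated <- unname(sum(category_fractions[
    c("hotspot", "novel", "pseudo", "decoy", "unmappable")]))
  structure(d, class = "sim_design")
}

# ---- low-level sequence helpers -------------------------------------------

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# insert `n_bulges` single random nucleotides into the interior of `x`
with_bulges <- function(x, n_bulges) {
  if (n_bulges == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sort(sample(seq(3L, length(ch) - 3L), n_bulges))
  for (k in rev(seq_along(pos))) {
    ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = pos[k])
  }
  paste(ch, collapse = "")
}

# does `f` (a hairpin_fold) carry `mature` (positions m1..m2) cleanly on one
# arm of its main stem with no unpaired run > max_bulge in that arm?
mature_arm_ok <- function(f, m1, m2, max_bulge = 4L) {
  g <- hairpin_geometry(f)
  if (g$n_stems == 0L) return(FALSE)
  st <- g$stems[[g$main]]
  on5 <- m1 >= st$arm5[1] && m2 <= st$arm5[2]
  on3 <- m1 >= st$arm3[1] && m2 <= st$arm3[2]
  if (!on5 && !on3) return(FALSE)
  bulge <- if (on5) st$max_bulge5 else st$max_bulge3
  bulge <= max_bulge
}

# build one clean miRNA-like hairpin: mature + loop + (bulged) complement
make_clean_hairpin <- function(mature_len, arm = c("5p", "3p"),
                               n_bulges = NULL, mfe_max = -20,
                               max_tries = 60L) {
  arm <- match.arg(arm)
  for (t in seq_len(max_tries)) {
    nb <- if (is.null(n_bulges)) sample(0:2, 1) else n_bulges
    mature <- rand_nt(mature_len)
    loop <- rand_nt(sample(8:12, 1))
    other <- with_bulges(revcomp_chr(mature), nb)
    if (arm == "5p") {
      prec <- paste0(mature, loop, other)
      m1 <- 1L; m2 <- mature_len
    } else {
      prec <- paste0(other, loop, mature)
      m1 <- nchar(other) + nchar(loop) + 1L
      m2 <- m1 + mature_len - 1L
    }
    f <- fold(prec)
    if (f$mfe < mfe_max && mature_arm_ok(f, m1, m2))
      return(list(precursor = prec, mature = mature, arm = arm,
                  mature_start = m1, mature_end = m2, mfe = f$mfe))
  }
  stop("failed to construct a criteria-passing hairpin in ", max_tries,
       " tries")
}

# for each base, the bases that can neither Watson-Crick nor GU pair
# with it (so planted internal loops stay unpaired under folding)
.nonpairing <- list(A = c("A", "C", "G"), C = c("A", "C", "T"),
                    G = c("A", "G"), T = c("C", "T"))

nonpairing_partner <- function(x) {
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  paste(vapply(ch, function(b) sample(.nonpairing[[b]], 1), character(1)),
        collapse = "")
}

# pseudo hairpin that *passes* the hairpin criteria (stable, small loops)
# but has interrupted, pseudo-like triplet composition: short perfect
# blocks separated by guaranteed-unpaired 2x2 internal loops.
make_pseudo_stable <- function(max_tries = 120L) {
  for (t in seq_len(max_tries)) {
    n_block <- sample(6:7, 1)
    blocks <- vapply(seq_len(n_block), function(i) rand_nt(sample(3:5, 1)),
                     character(1))
    gapL <- vapply(seq_len(n_block - 1), function(i) rand_nt(2), character(1))
    gapR <- vapply(gapL, nonpairing_partner, character(1))
    left <- paste0(paste0(blocks[-n_block], gapL, collapse = ""),
                   blocks[n_block])
    loop <- rand_nt(sample(6:9, 1))
    right <- paste0(
      revcomp_chr(blocks[n_block]),
      paste0(rev(mapply(function(b, g) paste0(g, revcomp_chr(b)),
                        blocks[-n_block], gapR)), collapse = ""))
    prec <- paste0(left, loop, right)
    m1 <- 2L; m2 <- min(nchar(left), m1 + 21L)
    f <- fold(prec)
    if (f$mfe >= -20 || !mature_arm_ok(f, m1, m2)) next
    # require genuinely interrupted stems: several unpaired positions in
    # the mature arm and no long perfect helix
    pt <- pair_table(f$structure)
    armpos <- seq(m1, m2)
    n_unp <- sum(pt[armpos] == 0)
    paired_runs <- rle(pt[seq_len(nchar(left))] > 0)
    longest <- max(c(0L, paired_runs$lengths[paired_runs$values]))
    if (n_unp >= 4L && longest <= 8L)
      return(list(precursor = prec, mature = substr(prec, m1, m2),
                  arm = "5p", mature_start = m1, mature_end = m2,
                  mfe = f$mfe))
  }
  stop("failed to construct a stable pseudo hairpin in ", max_tries, " tries")
}

# pseudo hairpin that folds but fails the stability criterion:
# short stem with a large internal loop, MFE in (-20, -5)
make_pseudo_loose <- function(max_tries = 80L) {
  for (t in seq_len(max_tries)) {
    b1 <- rand_nt(5); b2 <- rand_nt(5)
    il_l <- rand_nt(3); il_r <- rand_nt(3)
    loop <- rand_nt(sample(6:9, 1))
    prec <- paste0(b1, il_l, b2, loop, revcomp_chr(b2), il_r, revcomp_chr(b1))
    # pad with unstructured flanks so the locus looks precursor-sized
    prec <- paste0(rand_nt(6), prec, rand_nt(6))
    f <- fold(prec)
    if (f$mfe > -20 && f$mfe < -5) {
      m1 <- 7L; m2 <- min(nchar(prec) - 6L, m1 + 20L)
      return(list(precursor = prec, mature = substr(prec, m1, m2),
                  arm = "5p", mature_start = m1, mature_end = m2,
                  mfe = f$mfe))
    }
  }
  stop("failed to construct a loose pseudo hairpin in ", max_tries, " tries")
}

# ---- genome simulation ----------------------------------------------------

#' Simulate a toy genome with planted features and a truth manifest
#'
#' Builds a single-chromosome genome (default ~100 kb) containing, at
#' non-overlapping loci: known miRNA precursors, novel miRNA precursors
#' (all satisfying the three hairpin candidate criteria under the
#' package's own folding engine), criteria-passing and criteria-failing
#' pseudo hairpins, a decoy hairpin whose mature is in the known catalog,
#' other ncRNA loci (rRNA/tRNA/snRNA/snoRNA/scRNA/repeat/exon/intron) and
#' intergenic degradation hotspots.  Per-feature mean abundances (RPM,
#' per group) are drawn here so that the manifest fully determines the
#' expected library composition; novel and decoy miRNAs are
#' down-regulated in group C by `design$novel_fold_change`.
#'
#' @param design a [simulation_design()].
#' @param seed integer seed; identical `(design, seed)` give identical
#'   output.
#' @return a list with `genome` (a named [Biostrings::DNAStringSet] of
#'   length 1) and `manifest` (class `truth_manifest`): per-category
#'   feature tables (`known`, `novel`, `pseudo`, `decoy`, `ncrna`,
#'   `hotspot`), the known-mature `catalog`, `adapter`, `seed` and
#'   `genome_length`.
#' @export
simulate_genome <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(as.integer(seed))

  hp_row <- function(id, category, h) {
    data.frame(id = id, category = category, width = nchar(h$precursor),
               precursor = h$precursor, mature = h$mature, arm = h$arm,
               mature_offset1 = h$mature_start, mature_offset2 = h$mature_end,
               mfe = h$mfe, stringsAsFactors = FALSE)
  }
  known <- do.call(rbind, lapply(seq_len(design$n_known), function(i)
    hp_row(sprintf("known-%02d", i), "miRNA",
           make_clean_hairpin(sample(21:23, 1, prob = c(.25, .5, .25)),
                              sample(c("5p", "3p"), 1)))))
  novel <- if (design$n_novel > 0)
    do.call(rbind, lapply(seq_len(design$n_novel), function(i)
      hp_row(sprintf("novel-%02d", i), "novel",
             make_clean_hairpin(sample(21:23, 1, prob = c(.25, .5, .25)),
                                if (i %% 2) "5p" else "3p"))))
  pseudo <- NULL
  if (design$n_pseudo_stable > 0)
    pseudo <- do.call(rbind, lapply(seq_len(design$n_pseudo_stable),
      function(i) {
        r <- hp_row(sprintf("pseudo-s%02d", i), "pseudo", make_pseudo_stable())
        r$subtype <- "stable"; r
      }))
  if (design$n_pseudo_loose > 0) {
    loose <- do.call(rbind, lapply(seq_len(design$n_pseudo_loose),
      function(i) {
        r <- hp_row(sprintf("pseudo-l%02d", i), "pseudo", make_pseudo_loose())
        r$subtype <- "loose"; r
      }))
    pseudo <- rbind(pseudo, loose)
  }
  decoy <- if (design$n_decoy > 0)
    do.call(rbind, lapply(seq_len(design$n_decoy), function(i)
      hp_row(sprintf("decoy-%02d", i), "decoy",
             make_clean_hairpin(22L, "5p"))))

  nc_spec <- c(rRNA = 120L, tRNA = 72L, snRNA = 100L, snoRNA = 80L,
               scRNA = 90L, repeat_ = 150L, exon = 200L, intron = 300L)
  nc_n <- c(rRNA = 2L, tRNA = 3L, snRNA = 2L, snoRNA = 2L, scRNA = 1L,
            repeat_ = 2L, exon = 3L, intron = 2L)
  ncrna <- do.call(rbind, lapply(names(nc_spec), function(cat) {
    do.call(rbind, lapply(seq_len(nc_n[[cat]]), function(i)
      data.frame(id = sprintf("%s-%02d", sub("_$", "", cat), i),
                 category = cat, width = nc_spec[[cat]],
                 sequence = rand_nt(nc_spec[[cat]]),
                 stringsAsFactors = FALSE)))
  }))
  hotspot <- do.call(rbind, lapply(seq_len(design$n_hotspots), function(i)
    data.frame(id = sprintf("hotspot-%02d", i), category = "hotspot",
               width = 24L, sequence = rand_nt(24L),
               stringsAsFactors = FALSE)))

  # ---- placement: shuffled feature blocks separated by random background
  feats <- list(
    data.frame(id = known$id, category = known$category, width = known$width,
               sequence = known$precursor, stringsAsFactors = FALSE),
    if (!is.null(novel)) data.frame(id = novel$id, category = "novel",
                                    width = novel$width,
                                    sequence = novel$precursor,
                                    stringsAsFactors = FALSE),
    if (!is.null(pseudo)) data.frame(id = pseudo$id, category = "pseudo",
                                     width = pseudo$width,
                                     sequence = pseudo$precursor,
                                     stringsAsFactors = FALSE),
    if (!is.null(decoy)) data.frame(id = decoy$id, category = "decoy",
                                    width = decoy$width,
                                    sequence = decoy$precursor,
                                    stringsAsFactors = FALSE),
    ncrna[, c("id", "category", "width", "sequence")],
    hotspot[, c("id", "category", "width", "sequence")])
  feats <- do.call(rbind, feats)
  min_gap <- 60L
  need <- sum(feats$width) + (nrow(feats) + 1L) * min_gap
  if (design$genome_length < need)
    stop("genome too short to host all planted features: need at least ",
         need, " nt, have ", design$genome_length,
         " (deficit ", need - design$genome_length, " nt)")
  ord <- sample(nrow(feats))
  feats <- feats[ord, , drop = FALSE]
  slack <- design$genome_length - sum(feats$width) -
    (nrow(feats) + 1L) * min_gap
  cuts <- sort(sample(0:slack, nrow(feats) + 1L, replace = TRUE))
  extra <- diff(c(0L, cuts))
  extra[length(extra)] <- extra[length(extra)] +
    (slack - sum(diff(c(0L, cuts))))
  gaps <- min_gap + extra

  feats$strand <- sample(c("+", "-"), nrow(feats), replace = TRUE)
  pieces <- character(2L * nrow(feats) + 1L)
  starts <- integer(nrow(feats))
  pos <- 0L
  for (k in seq_len(nrow(feats))) {
    pieces[2L * k - 1L] <- rand_nt(gaps[k])
    pos <- pos + gaps[k]
    starts[k] <- pos + 1L
    planted <- if (feats$strand[k] == "+") feats$sequence[k] else
      revcomp_chr(feats$sequence[k])
    pieces[2L * k] <- planted
    pos <- pos + feats$width[k]
  }
  tail_len <- design$genome_length - pos
  pieces[length(pieces)] <- rand_nt(tail_len)
  genome_seq <- paste(pieces, collapse = "")
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chr1"

  feats$start <- starts
  feats$end <- starts + feats$width - 1L

  locate <- function(tab, base) {
    idx <- match(tab$id, feats$id)
    tab$start <- feats$start[idx]
    tab$end <- feats$end[idx]
    tab$strand <- feats$strand[idx]
    if (!is.null(tab$mature_offset1)) {
      plus <- tab$strand == "+"
      tab$mature_start <- ifelse(plus, tab$start + tab$mature_offset1 - 1L,
                                 tab$end - tab$mature_offset2 + 1L)
      tab$mature_end <- ifelse(plus, tab$start + tab$mature_offset2 - 1L,
                               tab$end - tab$mature_offset1 + 1L)
    }
    tab
  }
  known <- locate(known)
  if (!is.null(novel)) novel <- locate(novel)
  if (!is.null(pseudo)) pseudo <- locate(pseudo)
  if (!is.null(decoy)) decoy <- locate(decoy)
  ncrna <- locate(ncrna)
  hotspot <- locate(hotspot)

  # ---- per-feature abundances (RPM of clean reads, per group)
  cf <- design$category_fractions
  draw_rpm <- function(tab, cat_key) {
    if (is.null(tab) || nrow(tab) == 0) return(tab)
    w <- rlnorm(nrow(tab), 0, design$feature_sdlog)
    rpm <- 1e6 * cf[[cat_key]] * w / sum(w)
    tab$mean_rpm_H <- rpm
    tab$mean_rpm_C <- rpm
    tab
  }
  known <- draw_rpm(known, "miRNA")
  novel <- draw_rpm(novel, "novel")
  pseudo <- draw_rpm(pseudo, "pseudo")
  decoy <- draw_rpm(decoy, "decoy")
  hotspot <- draw_rpm(hotspot, "hotspot")
  ncrna$mean_rpm_H <- ncrna$mean_rpm_C <- 0
  for (cat in unique(ncrna$category)) {
    sel <- ncrna$category == cat
    w <- rlnorm(sum(sel), 0, design$feature_sdlog)
    ncrna$mean_rpm_H[sel] <- ncrna$mean_rpm_C[sel] <-
      1e6 * cf[[cat]] * w / sum(w)
  }
  # down-regulation of novel + decoy in the cancer group
  if (!is.null(novel)) novel$mean_rpm_C <- novel$mean_rpm_C *
      design$novel_fold_change
  if (!is.null(decoy)) decoy$mean_rpm_C <- decoy$mean_rpm_C *
      design$novel_fold_change

  # known-mature catalog: planted known matures + decoy matures + extras
  extras <- vapply(seq_len(20), function(i) rand_nt(sample(19:23, 1)),
                   character(1))
  catalog <- c(setNames(known$mature, known$id),
               if (!is.null(decoy)) setNames(decoy$mature, decoy$id),
               setNames(extras, sprintf("catalog-extra-%02d",
                                        seq_along(extras))))

  manifest <- structure(list(
    known = known, novel = novel, pseudo = pseudo, decoy = decoy,
    ncrna = ncrna, hotspot = hotspot, catalog = catalog,
    adapter = design$adapter, seed = as.integer(seed),
    genome_length = design$genome_length, design = design),
    class = "truth_manifest")
  list(genome = genome, manifest = manifest)
}

#' Planted annotated features as a GRanges
#'
#' Returns the annotation intervals a real analysis would obtain from
#' public databases: known miRNA precursors and the other ncRNA/repeat/
#' exon/intron loci.  Novel and pseudo hairpins, the decoy and the
#' degradation hotspots are deliberately absent (they are what the
#' discovery stage must find).
#'
#' @param manifest a `truth_manifest`.
#' @return a [GenomicRanges::GRanges] with a `category` metadata column.
#' @export
manifest_features <- function(manifest) {
  stopifnot(inherits(manifest, "truth_manifest"))
  tabs <- rbind(
    manifest$known[, c("id", "category", "start", "end", "strand")],
    manifest$ncrna[, c("id", "category", "start", "end", "strand")])
  cat <- sub("_$", "", tabs$category)
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(tabs$start, tabs$end),
                               strand = tabs$strand)
  gr$category <- ifelse(cat == "repeat", "repeat", cat)
  gr$ID <- tabs$id
  gr
}

#' Write the planted annotation to a GFF3 file
#'
#' @param manifest a `truth_manifest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest_gff <- function(manifest, path) {
  gr <- manifest_features(manifest)
  gr$type <- gr$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- library simulation ---------------------------------------------------

# per-feature sampling table from a manifest: id, category, kind
# (mature/fragment), sequence or locus, strand, rpm per group
feature_sampling_table <- function(manifest) {
  g <- function(tab, kind) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    data.frame(id = tab$id, category = tab$category, kind = kind,
               sequence = if (kind == "mature") tab$mature else tab$sequence,
               rpm_C = tab$mean_rpm_C, rpm_H = tab$mean_rpm_H,
               stringsAsFactors = FALSE)
  }
  rbind(g(manifest$known, "mature"), g(manifest$novel, "mature"),
        g(manifest$pseudo, "mature"), g(manifest$decoy, "mature"),
        g(manifest$ncrna, "fragment"), g(manifest$hotspot, "fragment"))
}

# simulate insert sequences for one feature
simulate_inserts <- function(feat, n) {
  if (n == 0L) return(character(0))
  if (feat$kind == "mature") {
    trim <- sample(c(2L, 1L, 0L), n, replace = TRUE, prob = c(.1, .2, .7))
    substring(feat$sequence, 1L, nchar(feat$sequence) - trim)
  } else {
    w <- nchar(feat$sequence)
    len <- sample(18:min(26L, w), n, replace = TRUE)
    start <- vapply(w - len + 1L, function(m) sample.int(m, 1L), integer(1))
    substring(feat$sequence, start, start + len - 1L)
  }
}

#' Simulate the replicated read libraries of the study design
#'
#' Draws, for every library (C1..Cn then H1..Hn), a multinomial sample of
#' `design$reads_per_library` reads over the manifest's features (at their
#' per-group mean RPM, multiplied by per-replicate log-normal noise),
#' unmappable background sequences, adapter-dimer contaminants,
#' low-quality reads and N-containing reads.  Every read is the insert
#' followed by the 3' adapter, truncated to `design$read_length`;
#' qualities are Phred+33.  Uniform substitution errors are applied at
#' `design$error_rate`.
#'
#' @param genome the genome from [simulate_genome()] (unused for read
#'   construction - inserts come from the manifest - but kept in the
#'   signature as the natural data-flow contract).
#' @param manifest the `truth_manifest`.
#' @param design the [simulation_design()].
#' @param seed integer seed.
#' @param outdir optional directory; when given, one FASTQ per library is
#'   written (`<lib>.fastq`) and paths are returned in `files`.
#' @return a list: `libraries` (named list with `sequence` and `quality`
#'   character vectors per library), `groups` (named list of library
#'   names per group), `truth` (list with per-feature `counts` matrix,
#'   `clean_reads`, `rpm` truth matrix over clean reads), and optionally
#'   `files`.
#' @export
simulate_libraries <- function(genome, manifest, design, seed,
                               outdir = NULL) {
  stopifnot(inherits(manifest, "truth_manifest"),
            inherits(design, "sim_design"))
  set.seed(as.integer(seed))
  nrep <- design$n_replicates_per_group
  libs <- c(paste0("C", seq_len(nrep)), paste0("H", seq_len(nrep)))
  groups <- list(C = paste0("C", seq_len(nrep)),
                 H = paste0("H", seq_len(nrep)))

  ftab <- feature_sampling_table(manifest)
  nf <- nrow(ftab)
  special <- c(unmappable = NA, contaminant = design$contaminant_fraction,
               lowqual = design$lowqual_fraction,
               ambiguous = design$ambiguous_fraction)
  clean_frac <- 1 - sum(special[-1])

  counts <- matrix(0L, nf + 4L, length(libs),
                   dimnames = list(c(ftab$id, names(special)), libs))
  out <- list()
  qual_hi <- function(len) strrep("I", len)

  for (lib in libs) {
    grp <- substr(lib, 1, 1)
    rpm <- if (grp == "C") ftab$rpm_C else ftab$rpm_H
    w <- (rpm / 1e6) * rlnorm(nf, 0, design$replicate_sdlog)
    un <- max(0, 1 - sum(w)) # unmappable background takes the remainder
    probs <- c(w * clean_frac, un * clean_frac,
               special["contaminant"], special["lowqual"],
               special["ambiguous"])
    cnt <- as.integer(rmultinom(1, design$reads_per_library,
                                probs / sum(probs)))
    counts[, lib] <- cnt

    inserts <- character(0)
    for (k in seq_len(nf)) {
      inserts <- c(inserts, simulate_inserts(ftab[k, ], cnt[k]))
    }
    # unmappable background: random sequences with a miRNA-sized mode
    n_un <- cnt[nf + 1L]
    if (n_un > 0) {
      lens <- sample(18:26, n_un, replace = TRUE,
                     prob = c(1, 2, 3, 5, 8, 5, 3, 2, 1))
      inserts <- c(inserts, vapply(lens, rand_nt, character(1)))
    }
    n_clean <- length(inserts)
    reads <- substr(paste0(inserts, design$adapter, design$adapter),
                    1L, design$read_length)
    quals <- rep(qual_hi(design$read_length), n_clean)

    # adapter-dimer contaminants
    n_dimer <- cnt[nf + 2L]
    if (n_dimer > 0) {
      reads <- c(reads, rep(substr(strrep(design$adapter, 3L), 1L,
                                   design$read_length), n_dimer))
      quals <- c(quals, rep(qual_hi(design$read_length), n_dimer))
    }
    # low-quality reads: one base below Phred 20
    n_lq <- cnt[nf + 3L]
    if (n_lq > 0) {
      lq_len <- sample(20:24, n_lq, replace = TRUE)
      lq_reads <- substr(paste0(vapply(lq_len, rand_nt, character(1)),
                                design$adapter, design$adapter),
                         1L, design$read_length)
      # the sub-threshold base must sit inside the insert, or trimming
      # would rescue the read
      lq_quals <- vapply(lq_len, function(len) {
                           q <- qual_hi(design$read_length)
                           p <- sample.int(len, 1L)
                           substr(q, p, p) <- "#"
                           q
                         }, character(1))
      reads <- c(reads, lq_reads)
      quals <- c(quals, lq_quals)
    }
    # ambiguous reads: one N in the insert
    n_amb <- cnt[nf + 4L]
    if (n_amb > 0) {
      amb <- vapply(seq_len(n_amb), function(i) {
        s <- rand_nt(22L)
        p <- sample.int(22L, 1L)
        paste0(substr(s, 1, p - 1), "N", substr(s, p + 1, 22L))
      }, character(1))
      amb_reads <- substr(paste0(amb, design$adapter, design$adapter),
                          1L, design$read_length)
      reads <- c(reads, amb_reads)
      quals <- c(quals, rep(qual_hi(design$read_length), n_amb))
    }

    # uniform substitution errors
    if (design$error_rate > 0) {
      hit <- which(runif(length(reads)) < design$error_rate)
      for (i in hit) {
        p <- sample.int(nchar(reads[i]), 1L)
        substr(reads[i], p, p) <- sample(c("A", "C", "G", "T"), 1L)
      }
    }
    ord <- sample(length(reads))
    out[[lib]] <- list(sequence = reads[ord], quality = quals[ord])
  }

  clean_reads <- design$reads_per_library -
    colSums(counts[c("contaminant", "lowqual", "ambiguous"), , drop = FALSE])
  rpm_truth <- sweep(counts[seq_len(nf), , drop = FALSE], 2,
                     clean_reads, "/") * 1e6

  res <- list(libraries = out, groups = groups,
              truth = list(counts = counts, clean_reads = clean_reads,
                           rpm = rpm_truth, features = ftab))
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    files <- setNames(file.path(outdir, paste0(libs, ".fastq")), libs)
    for (lib in libs) {
      x <- Biostrings::DNAStringSet(out[[lib]]$sequence)
      names(x) <- paste0(lib, ".", seq_along(x))
      Biostrings::writeXStringSet(
        x, files[[lib]], format = "fastq",
        qualities = Biostrings::BStringSet(out[[lib]]$quality))
    }
    res$files <- files
  }
  res
}

#' Simulate a qPCR Ct table with a known true fold change
#'
#' Per-subject target and reference (U6-like) Ct values such that the
#' group-level `2^-ddCt` recovers `fold_change` (patients relative to
#' controls) up to sampling noise: patient dCt is shifted by
#' `-log2(fold_change)` cycles relative to controls.
#'
#' @param n_patients,n_controls subjects per group.
#' @param fold_change true patient/control expression ratio (> 0).
#' @param sd_ct per-subject dCt standard deviation in cycles.
#' @param seed integer seed.
#' @param dct_control_mean,ct_reference_mean location parameters (cycles).
#' @return a data.frame: `subject`, `group` ("patient"/"control"),
#'   `ct_target`, `ct_reference`.
#' @export
simulate_ct_table <- function(n_patients = 100L, n_controls = 100L,
                              fold_change = 0.4, sd_ct = 0.3, seed = 1L,
                              dct_control_mean = 5, ct_reference_mean = 18) {
  if (fold_change <= 0) stop("fold_change must be positive")
  set.seed(as.integer(seed))
  n <- n_patients + n_controls
  group <- rep(c("patient", "control"), c(n_patients, n_controls))
  dct_mean <- ifelse(group == "patient",
                     dct_control_mean - log2(fold_change), dct_control_mean)
  dct <- rnorm(n, dct_mean, sd_ct)
  ct_ref <- rnorm(n, ct_reference_mean, 0.2)
  data.frame(subject = sprintf("S%03d", seq_len(n)), group = group,
             ct_target = ct_ref + dct, ct_reference = ct_ref,
             stringsAsFactors = FALSE)
}

#' Simulate a labelled real/pseudo hairpin training set
#'
#' Generates criteria-passing miRNA-like precursors ("real") and pseudo
#' hairpins (half stable-but-interrupted, half unstable) for training and
#' evaluating the triplet-feature classifier.
#'
#' @param n_real,n_pseudo class sizes (>= 1).
#' @param seed integer seed.
#' @return a data.frame: `id`, `class` ("real"/"pseudo"), `sequence`.
#' @export
simulate_hairpin_set <- function(n_real = 30L, n_pseudo = 30L, seed = 1L) {
  set.seed(as.integer(seed))
  real <- vapply(seq_len(n_real), function(i)
    make_clean_hairpin(sample(21:23, 1), sample(c("5p", "3p"), 1))$precursor,
    character(1))
  n_st <- ceiling(n_pseudo / 2)
  ps <- c(vapply(seq_len(n_st), function(i) make_pseudo_stable()$precursor,
                 character(1)),
          vapply(seq_len(n_pseudo - n_st), function(i)
            make_pseudo_loose()$precursor, character(1)))
  data.frame(id = c(sprintf("real-%03d", seq_len(n_real)),
                    sprintf("pseudo-%03d", seq_len(n_pseudo))),
             class = rep(c("real", "pseudo"), c(n_real, n_pseudo)),
             sequence = c(real, ps), stringsAsFactors = FALSE)
}
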