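#' Clean a raw small-RNA library
#'
#' Applies the standard small-RNA cleaning cascade: locate the 3' adapter
#' (earliest prefix match with at most 1 mismatch and at least 6 nt
#' overlap, so partial adapters at the read end are found), trim it,
#' discard adapter-dimer contaminants (insert shorter than `min_len`),
#' reads with no adapter whose full length exceeds `max_len`, reads with
#' any base below `min_qual` (Phred+33) or any ambiguous base, and reads
#' outside `[min_len, max_len]` after trimming.
#'
#' @param reads a FASTQ file path, or a list with `sequence` and
#'   `quality` character vectors (as produced by [simulate_libraries()]).
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_len,max_len insert length window kept (default 18-30 nt).
#' @param min_qual minimum per-base Phred quality (default 20).
#' @return a list with `sequence` (cleaned inserts) and `summary`, a
#'   one-row data.frame: `total_reads`, `clean_reads`, `clean_fraction`,
#'   `discarded_no_adapter`, `discarded_contaminant`,
#'   `discarded_lowqual`, `discarded_ambiguous`, `discarded_length`.
#' @export
clean_reads <- function(reads, adapter, min_len = 18L, max_len = 30L,
                        min_qual = 20L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (is.character(reads) && length(reads) == 1L) {
    x <- tryCatch(
      Biostrings::readDNAStringSet(reads, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ '", reads, "': ",
                               conditionMessage(e)))
    seqs <- as.character(x)
    quals <- as.character(S4Vectors::mcols(x)$qualities)
  } else if (is.list(reads) && !is.null(reads$sequence)) {
    seqs <- as.character(reads$sequence)
    quals <- if (is.null(reads$quality))
      strrep("I", nchar(seqs)) else as.character(reads$quality)
  } else {
    stop("'reads' must be a FASTQ path or a list(sequence, quality)")
  }
  names(seqs) <- NULL
  total <- length(seqs)
  adapter <- toupper(adapter)

  pos <- find_adapter(seqs, adapter, min_overlap = 6L, max_mismatch = 1L)
  no_adapter <- is.na(pos)
  if (total > 0 && all(no_adapter))
    warning("adapter not found in any read")
  ins_len <- ifelse(no_adapter, nchar(seqs), pos - 1L)
  insert <- substr(seqs, 1L, ins_len)
  iqual <- substr(quals, 1L, ins_len)

  too_long <- ins_len > max_len # includes untrimmed reads longer than max
  contaminant <- !no_adapter & ins_len < min_len
  bad_qual <- qual_below(iqual, min_qual)
  bad_base <- grepl("[^ACGT]", toupper(insert))
  keep <- !too_long & !contaminant & !bad_qual & !bad_base &
    ins_len >= min_len
  clean <- toupper(insert[keep])

  # disjoint discard buckets, in filtering order
  b_noad <- no_adapter & too_long
  b_cont <- contaminant
  b_len <- !keep & !b_noad & !b_cont & (too_long | ins_len < min_len)
  b_qual <- !keep & !b_noad & !b_cont & !b_len & bad_qual
  b_amb <- !keep & !b_noad & !b_cont & !b_len & !b_qual & bad_base
  summary <- data.frame(
    total_reads = total,
    clean_reads = length(clean),
    clean_fraction = if (total > 0) length(clean) / total else NA_real_,
    discarded_no_adapter = sum(b_noad),
    discarded_contaminant = sum(b_cont),
    discarded_lowqual = sum(b_qual),
    discarded_ambiguous = sum(b_amb),
    discarded_length = sum(b_len))
  list(sequence = clean, summary = summary)
}

# earliest start of a 3' adapter occurrence: prefix of `adapter` matching
# at position p with <= max_mismatch mismatches and >= min_overlap overlap.
# Returns NA where none found.  Vectorised over reads via a half-exact
# (pigeonhole) prefilter: any match with <= 1 mismatch has at least one
# exactly-matching half.
find_adapter <- function(seqs, adapter, min_overlap = 6L, max_mismatch = 1L) {
  n <- length(seqs)
  pos <- rep(NA_integer_, n)
  if (n == 0L) return(pos)
  alen <- nchar(adapter)
  maxlen <- max(nchar(seqs))
  for (p in seq_len(max(0L, maxlen - min_overlap + 1L))) {
    todo <- is.na(pos) & nchar(seqs) - p + 1L >= min_overlap
    if (!any(todo)) next
    ov <- pmin(alen, nchar(seqs) - p + 1L)
    pre <- substr(rep(adapter, n), 1L, ov) # adapter prefix per read
    sub <- substr(seqs, p, p + ov - 1L)
    h <- ov %/% 2L
    e1 <- substr(sub, 1L, h) == substr(pre, 1L, h)
    e2 <- substr(sub, h + 1L, ov) == substr(pre, h + 1L, ov)
    cand <- which(todo & (e1 | e2))
    if (!length(cand)) next
    exact <- cand[e1[cand] & e2[cand]]
    pos[exact] <- p
    rest <- setdiff(cand, exact)
    if (length(rest)) {
      mm <- mapply(function(a, b) {
        sum(utf8ToInt(a) != utf8ToInt(b))
      }, sub[rest], pre[rest], USE.NAMES = FALSE)
      hit <- rest[mm <= max_mismatch]
      pos[hit] <- p
    }
  }
  pos
}

# TRUE where any base of the quality string is below `min_qual` (Phred+33)
qual_below <- function(quals, min_qual) {
  if (min_qual <= 0) return(rep(FALSE, length(quals)))
  bad_max <- 33L + as.integer(min_qual) - 1L
  cls <- sprintf("[\\x21-\\x%02x]", bad_max)
  res <- grepl(cls, quals, perl = TRUE)
  res[nchar(quals) == 0L] <- FALSE
  res
}

#' Collapse cleaned libraries to unique tags with per-library counts
#'
#' @param libraries named list of cleaned read vectors (or of
#'   [clean_reads()] results).
#' @return a data.frame with `sequence` plus one integer count column per
#'   library; every row has at least one positive count and column sums
#'   equal the libraries' clean read totals.
#' @export
collapse_to_tags <- function(libraries) {
  if (is.null(names(libraries)) || any(!nzchar(names(libraries))))
    stop("'libraries' must be a named list")
  seqs <- lapply(libraries, function(x)
    if (is.list(x)) x$sequence else as.character(x))
  u <- sort(unique(unlist(seqs, use.names = FALSE)))
  tab <- data.frame(sequence = u, stringsAsFactors = FALSE)
  for (lib in names(seqs)) {
    tab[[lib]] <- tabulate(match(seqs[[lib]], u), nbins = length(u))
  }
  tab
}

#' Length distribution of a library's clean reads
#'
#' @param tags tag table from [collapse_to_tags()].
#' @param library column name; `NULL` sums all libraries.
#' @param range lengths reported (default 18-30 nt).
#' @return named integer vector of read counts per length.
#' @export
length_distribution <- function(tags, library = NULL, range = 18:30) {
  counts <- if (is.null(library)) {
    rowSums(tags[, setdiff(names(tags), "sequence"), drop = FALSE])
  } else {
    if (!library %in% names(tags)) stop("no library '", library, "' in tags")
    tags[[library]]
  }
  len <- nchar(tags$sequence)
  out <- setNames(integer(length(range)), range)
  agg <- tapply(counts, len, sum)
  hit <- intersect(names(agg), names(out))
  out[hit] <- as.integer(agg[hit])
  out
}

#' Tags and reads shared between two libraries
#'
#' `pct_common_unique` is the percentage of unique tags present in both
#' libraries among tags present in either (a Jaccard index x 100).
#' `pct_common_total` is the percentage of reads carried by those shared
#' tags among all clean reads of the two libraries combined.
#'
#' @param tags tag table from [collapse_to_tags()].
#' @param libA,libB library column names.
#' @return a one-row data.frame: `pct_common_unique`, `pct_common_total`,
#'   `n_common`, `n_union`.  Both percentages are `NA` when the union is
#'   empty.
#' @export
shared_tag_stats <- function(tags, libA, libB) {
  for (l in c(libA, libB))
    if (!l %in% names(tags)) stop("no library '", l, "' in tags")
  a <- tags[[libA]] > 0
  b <- tags[[libB]] > 0
  union <- a | b
  if (!any(union))
    return(data.frame(pct_common_unique = NA_real_,
                      pct_common_total = NA_real_,
                      n_common = 0L, n_union = 0L))
  common <- a & b
  total <- sum(tags[[libA]][union]) + sum(tags[[libB]][union])
  shared <- sum(tags[[libA]][common]) + sum(tags[[libB]][common])
  data.frame(pct_common_unique = 100 * sum(common) / sum(union),
             pct_common_total = 100 * shared / total,
             n_common = sum(common), n_union = sum(union))
}
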