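# Independent oracles used across the test suite.  These deliberately
# avoid the code paths they check: structure enumeration is recursive
# set construction + structure_energy() loop decomposition (not the DP),
# counting oracles are naive tallies, mapping uses fixed-string search.

# all secondary structures of length n as pair lists c(i1,j1,i2,j2,...),
# with every pair spanning >= 4 (hairpin loops >= 3 nt)
enum_structures <- function(n) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i + 1 < 5) return(list(integer(0)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- rec(i + 1, j) # i unpaired
    for (k in (i + 4):j) {
      inner <- rec(i + 1, k - 1)
      rest <- rec(k + 1, j)
      for (a in inner) for (b in rest)
        out[[length(out) + 1L]] <- c(i, k, a, b)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

pairs_to_db <- function(pl, n) {
  s <- rep(".", n)
  if (length(pl)) {
    s[pl[seq(1, length(pl), 2)]] <- "("
    s[pl[seq(2, length(pl), 2)]] <- ")"
  }
  paste(s, collapse = "")
}

# brute-force MFE: minimum structure_energy over all enumerated
# structures (structures with forbidden pairs score +Inf)
oracle_mfe <- function(seq) {
  n <- nchar(seq)
  es <- vapply(enum_structures(n), function(p) {
    tryCatch(structure_energy(seq, pairs_to_db(p, n)),
             error = function(e) Inf)
  }, numeric(1))
  min(0, min(es))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# naive per-position triplet tally
oracle_triplets <- function(sequence, structure) {
  rna <- chartr("T", "U", toupper(sequence))
  s <- strsplit(chartr("()", "((", structure), "")[[1]]
  b <- strsplit(rna, "")[[1]]
  pats <- c("...", "..(", ".(.", ".((", "(..", "(.(", "((.", "(((")
  feats <- as.vector(outer(pats, c("A", "C", "G", "U"),
                           function(p, bb) paste0(bb, p)))
  cnt <- setNames(numeric(32), feats)
  for (i in 2:(length(s) - 1)) {
    key <- paste0(b[i], s[i - 1], s[i], s[i + 1])
    cnt[key] <- cnt[key] + 1
  }
  cnt / (length(s) - 2)
}

# exact-count tag oracle
oracle_tags <- function(libs) {
  u <- sort(unique(unlist(libs)))
  out <- data.frame(sequence = u, stringsAsFactors = FALSE)
  for (l in names(libs)) out[[l]] <- vapply(u, function(s)
    sum(libs[[l]] == s), numeric(1))
  out
}

# fixed-string mapping oracle on both strands
oracle_map <- function(tag, genome_chr) {
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
    m <- gregexpr(q, genome_chr, fixed = TRUE)[[1]]
    if (m[1] != -1)
      hits[[strand]] <- data.frame(start = as.integer(m), strand = strand)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), strand = character(0))
}
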