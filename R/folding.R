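#' Predict the minimum free energy secondary structure of an RNA
#'
#' Dynamic-programming fold under the built-in nearest-neighbour model
#' (see [rna_energy_params()]): Watson-Crick and GU wobble pairs, pair
#' stacking energies, hairpin/bulge/internal loop initiation penalties and
#' an affine multiloop term.  Hairpin loops hold at least 3 unpaired
#' nucleotides; two-way loops are capped at `params$max_loop` unpaired
#' nucleotides.  When no structure improves on the open chain the result
#' is the all-dot structure with an MFE of exactly 0.
#'
#' `T` is normalised to `U` on input; the returned `sequence` keeps the
#' caller's alphabet.
#'
#' @param sequence a single nucleotide string (ACGU/ACGT, case
#'   insensitive), typically 40-300 nt for precursor work; shorter
#'   sequences are accepted and may simply fail to pair.
#' @param params energy parameter set from [rna_energy_params()].
#' @return an object of class `hairpin_fold`: a list with `sequence`,
#'   dot-bracket `structure`, and `mfe` in kcal/mol (<= 0).
#' @seealso [structure_energy()] to score an explicit structure under the
#'   same model, [hairpin_geometry()] for stem-loop anatomy.
#' @examples
#' fold("GGGGGAAACCCCC")
#' @export
fold <- function(sequence, params = default_energy_params()) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single nucleotide string")
  raw <- toupper(sequence)
  rna <- chartr("T", "U", raw)
  if (nchar(rna) == 0L) stop("'sequence' is empty")
  if (grepl("[^ACGU]", rna))
    stop("non-nucleotide character in sequence: ",
         gsub("[ACGU]", "", rna))
  if (nchar(rna) > params$max_size)
    stop("sequence longer than params$max_size (", params$max_size, " nt)")
  enc <- match(strsplit(rna, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
  res <- c_fold(enc, params$stack, params$hairpin, params$bulge,
                params$internal, params$asym_coef, params$asym_max,
                params$max_loop, params$ml_init, params$ml_branch,
                params$ml_unpaired)
  structure(list(sequence = raw, structure = res$structure,
                 mfe = round(res$mfe, 6)),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("MFE: %.2f kcal/mol\n", x$mfe))
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector: `p[i]` is the partner of position `i`, or 0.
#' @keywords internal
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c(".", "(", ")")))
    stop("structure may only contain '.', '(' and ')'")
  p <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced structure: unmatched ')' at ", i)
      j <- open[length(open)]
      open <- open[-length(open)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(open)) stop("unbalanced structure: unmatched '(' at ",
                         open[length(open)])
  p
}

#' Free energy of an explicit secondary structure
#'
#' Scores a given dot-bracket structure for a sequence under the same
#' nearest-neighbour model as [fold()], by loop decomposition: each closing
#' pair contributes a hairpin, stack/bulge/internal-loop, or multiloop
#' term; the external loop is free.  This is an independent evaluation
#' path from the DP recursions and is used as the enumeration oracle for
#' the folding engine.
#'
#' @param sequence nucleotide string.
#' @param structure dot-bracket string of the same length.
#' @param params energy parameter set.
#' @return energy in kcal/mol (0 for the open chain).
#' @export
structure_energy <- function(sequence, structure,
                             params = default_energy_params()) {
  rna <- chartr("T", "U", toupper(sequence))
  if (grepl("[^ACGU]", rna)) stop("non-nucleotide character in sequence")
  if (nchar(rna) != nchar(structure))
    stop("sequence and structure lengths differ")
  p <- pair_table(structure)
  n <- length(p)
  base <- strsplit(rna, "", fixed = TRUE)[[1]]
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  ptype <- function(i, j) {
    t <- paste0(base[i], base[j])
    if (!t %in% pairs) stop("non-canonical pair ", t, " at (", i, ",", j, ")")
    t
  }
  opening <- which(p > seq_len(n))
  e <- 0
  for (i in opening) {
    j <- p[i]
    # direct children of (i,j)
    kids <- integer(0)
    k <- i + 1
    while (k < j) {
      if (p[k] > k) {
        kids <- c(kids, k)
        k <- p[k] + 1
      } else if (p[k] != 0 && p[k] < k) {
        stop("crossing pairs in structure") # cannot happen with pair_table
      } else {
        k <- k + 1
      }
    }
    pt <- ptype(i, j)
    if (length(kids) == 0L) {
      if (j - i - 1 < params$min_hairpin)
        stop("hairpin loop shorter than ", params$min_hairpin, " nt at (",
             i, ",", j, ")")
      e <- e + params$hairpin[j - i - 1]
    } else if (length(kids) == 1L) {
      k <- kids[1]; l <- p[k]
      u1 <- k - i - 1; u2 <- j - l - 1
      ptin <- ptype(k, l)
      if (u1 == 0 && u2 == 0) {
        e <- e + params$stack[pt, ptin]
      } else if (u1 == 0 || u2 == 0) {
        e <- e + params$bulge[u1 + u2]
      } else {
        e <- e + params$internal[u1 + u2] +
          min(params$asym_max, params$asym_coef * abs(u1 - u2))
      }
    } else {
      unpaired <- (j - i - 1) - sum(p[kids] - kids + 1)
      e <- e + params$ml_init + params$ml_branch * (length(kids) + 1) +
        params$ml_unpaired * unpaired
    }
  }
  unname(e)
}

#' Stem-loop anatomy of a folded structure
#'
#' Decomposes a dot-bracket structure into its stems.  A *stem* is a
#' maximal chain of nested pairs in which every pair encloses exactly one
#' inner branch, terminating at a hairpin loop; bulges and internal loops
#' interrupt the helix but not the chain.  The *main* stem is the one with
#' the most pairs.  A structure is reported as a simple hairpin only when
#' it has a single hairpin loop and no multiloop.
#'
#' @param fold a `hairpin_fold` object from [fold()], or a dot-bracket
#'   string.
#' @return a list with `n_stems`, `n_hairpin_loops`, `any_multiloop`,
#'   `is_hairpin`, `main` (index of the main stem) and `stems`, a list of
#'   per-stem records: `outer` and `inner` pair positions, `loop` span and
#'   `loop_size`, `n_pairs`, `arm5`/`arm3` position ranges, and
#'   `max_bulge5`/`max_bulge3`, the largest unpaired run inside each arm.
#' @export
hairpin_geometry <- function(fold) {
  db <- if (inherits(fold, "hairpin_fold")) fold$structure else
    as.character(fold)
  p <- pair_table(db)
  n <- length(p)
  opening <- which(p > seq_len(n))
  if (!length(opening))
    return(list(n_stems = 0L, n_hairpin_loops = 0L, any_multiloop = FALSE,
                is_hairpin = FALSE, main = NA_integer_, stems = list()))

  # parent pair (opening position) of each pair, via scan
  parent <- setNames(rep(0L, length(opening)), opening)
  nchild <- setNames(rep(0L, length(opening)), opening)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (p[i] > i) {
      if (length(stk)) {
        parent[[as.character(i)]] <- stk[length(stk)]
        nchild[[as.character(stk[length(stk)])]] <-
          nchild[[as.character(stk[length(stk)])]] + 1L
      }
      stk <- c(stk, i)
    } else if (p[i] != 0 && p[i] < i) {
      stk <- stk[-length(stk)]
    }
  }

  innermost <- opening[nchild[as.character(opening)] == 0L]
  max_run <- function(pos) {
    if (!length(pos)) return(0L)
    un <- p[pos] == 0L
    if (!any(un)) return(0L)
    r <- rle(un)
    max(r$lengths[r$values])
  }
  stems <- lapply(innermost, function(h) {
    chain <- h
    cur <- h
    repeat {
      par <- parent[[as.character(cur)]]
      if (par == 0L || nchild[[as.character(par)]] != 1L) break
      chain <- c(par, chain)
      cur <- par
    }
    top <- chain[1]
    list(outer = c(top, p[top]), inner = c(h, p[h]),
         loop = c(h + 1L, p[h] - 1L), loop_size = p[h] - h - 1L,
         n_pairs = length(chain),
         arm5 = c(top, h), arm3 = c(p[h], p[top]),
         max_bulge5 = max_run(seq(top, h)),
         max_bulge3 = max_run(seq(p[h], p[top])))
  })
  any_ml <- any(nchild[as.character(opening)] >= 2L)
  npairs <- vapply(stems, function(s) s$n_pairs, integer(1))
  list(n_stems = length(stems),
       n_hairpin_loops = length(innermost),
       any_multiloop = any_ml,
       is_hairpin = length(innermost) == 1L && !any_ml,
       main = which.max(npairs),
       stems = stems)
}
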