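## Nested secondary-structure prediction by base-pair maximisation
## (Nussinov dynamic programming) and quantification of the structural
## change caused by a single editing event. Deterministic by
## construction: the traceback prefers the pairing branch and, among
## equally good partners, the smallest one.

.pairOK <- function(a, b, allowGU) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
  if (allowGU)
    wc <- wc | (a == "G" & b == "U") | (a == "U" & b == "G")
  wc
}

#' Fold an RNA by base-pair maximisation
#'
#' Computes a nested structure with the maximum number of Watson-Crick
#' (optionally plus G.U wobble) base pairs, subject to a minimum hairpin
#' loop size, by Nussinov dynamic programming with a deterministic
#' traceback. This is a combinatorial stand-in for thermodynamic
#' folding: it demonstrates whether an edit can rewire pairing, not the
#' minimum-free-energy structure.
#'
#' @param sequence RNA sequence over A, C, G, U (case-insensitive;
#'   character or [Biostrings::RNAString]).
#' @param minLoop Minimum number of unpaired bases enclosed by a pair
#'   (default 3, the standard steric constraint).
#' @param allowGU Allow G.U wobble pairs (default TRUE).
#' @return An [RNAStructure-class] object.
#' @examples
#' foldRNA("GGGAAAACCC")
#' @export
foldRNA <- function(sequence, minLoop = 3, allowGU = TRUE) {
  s <- toupper(as.character(sequence))
  if (!nzchar(s)) stop("sequence must have length >= 1")
  if (grepl("[^ACGU]", s))
    stop("invalid letters in RNA sequence (expected A, C, G, U)")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  M <- matrix(0L, n, n)
  if (n >= minLoop + 2L) {
    for (span in (minLoop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i + 1L, j]                       # i unpaired
        ks <- (i + minLoop + 1L):j
        ks <- ks[.pairOK(ch[i], ch[ks], allowGU)]
        for (k in ks) {                            # i paired with k
          inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
          outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
          v <- inner + 1L + outer
          if (v > best) best <- v
        }
        M[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  stack <- list(c(1L, n))
  while (length(stack) && n > 1L) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= minLoop) next
    target <- M[i, j]
    if (target == 0L) next
    paired <- FALSE
    ks <- (i + minLoop + 1L):j
    ks <- ks[.pairOK(ch[i], ch[ks], allowGU)]
    for (k in ks) {  # pairing branch first; smallest partner wins ties
      inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
      outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
      if (inner + 1L + outer == target) {
        pairs <- rbind(pairs, c(i, k))
        if (k - 1L >= i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  methods::new("RNAStructure", sequence = Biostrings::RNAString(s),
               pairs = pairs, dotBracket = pairsToDotBracket(pairs, n),
               minLoop = minLoop)
}

#' Convert a pair set to dot-bracket notation
#' @param pairs Two-column integer matrix of (i, j) pairs, i < j.
#' @param n Sequence length.
#' @return Dot-bracket string of length `n`.
#' @export
pairsToDotBracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a pair set
#' @param db Dot-bracket string over `.`, `(`, `)`.
#' @return Two-column integer matrix of (i, j) pairs, sorted by `i`.
#' @export
dotBracketToPairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c(".", "(", ")")))
    stop("invalid dot-bracket character")
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(ch)) {
    if (ch[k] == "(") open <- c(open, k)
    else if (ch[k] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced dot-bracket string")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Structural change caused by a single edit
#'
#' Folds the sequence before and after a single-base edit with identical
#' parameters and counts how many base pairs differ (size of the
#' symmetric difference of the two pair sets) -- the quantity used to
#' judge whether an rRNA editing event rewires the predicted structure.
#'
#' @param sequence RNA sequence carrying `baseBefore` at `editPosition`.
#' @param editPosition 1-based position of the edit.
#' @param baseBefore,baseAfter The pre- and post-edit bases (must
#'   differ).
#' @param minLoop,allowGU Folding parameters, see [foldRNA()].
#' @return List with `before` and `after` ([RNAStructure-class]),
#'   `pairsBefore`, `pairsAfter` (pair counts) and `changedPairCount`.
#' @export
structureDelta <- function(sequence, editPosition, baseBefore, baseAfter,
                           minLoop = 3, allowGU = TRUE) {
  s <- toupper(as.character(sequence))
  baseBefore <- toupper(baseBefore); baseAfter <- toupper(baseAfter)
  if (editPosition < 1L || editPosition > nchar(s))
    stop("editPosition outside the sequence")
  if (substr(s, editPosition, editPosition) != baseBefore)
    stop("sequence carries '", substr(s, editPosition, editPosition),
         "' at position ", editPosition, ", not '", baseBefore, "'")
  if (baseBefore == baseAfter)
    stop("baseBefore and baseAfter must differ")
  after <- s
  substr(after, editPosition, editPosition) <- baseAfter
  fb <- foldRNA(s, minLoop, allowGU)
  fa <- foldRNA(after, minLoop, allowGU)
  key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)
  changed <- length(setdiff(key(fb@pairs), key(fa@pairs))) +
    length(setdiff(key(fa@pairs), key(fb@pairs)))
  list(before = fb, after = fa, pairsBefore = nrow(fb@pairs),
       pairsAfter = nrow(fa@pairs), changedPairCount = changed)
}

#' Write a structure in Vienna format
#'
#' Plain-text Vienna layout: a `>` header, the sequence line and the
#' dot-bracket line.
#'
#' @param structure An [RNAStructure-class] object.
#' @param path Output path.
#' @param name Record name for the header line.
#' @return Invisibly, the path.
#' @export
writeVienna <- function(structure, path, name = "structure") {
  writeLines(c(paste0(">", name),
               as.character(structure@sequence),
               structure@dotBracket), path)
  invisible(path)
}
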