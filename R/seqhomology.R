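# Global pairwise sequence alignment with affine gaps (Gotoh's three-state
# dynamic program), used for effector-domain homology comparisons between
# GntR-family regulators.

#' BLOSUM62 substitution matrix
#'
#' Fetched from the Biostrings data set at call time.
#'
#' @return The BLOSUM62 integer matrix (rows/columns named by residue).
#' @export
blosum62 <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("blosum62() needs the Biostrings package")
  }
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta() needs the Biostrings package")
  }
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Global alignment with affine gap penalties (Needleman-Wunsch/Gotoh)
#'
#' Computes the optimal global alignment score under an affine gap model
#' where a gap run of length L costs `gap_open + (L - 1) * gap_extend`
#' (the first gap position pays the opening penalty). Traceback ties are
#' resolved deterministically: diagonal over up (gap in `seq_b`) over left
#' (gap in `seq_a`). Defaults mirror the EMBOSS needle setup (BLOSUM62,
#' gap open 10, gap extend 0.5).
#'
#' @param seq_a,seq_b Amino-acid strings (non-empty; letters must exist in
#'   the matrix).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return An `alignment_result`: `aligned_a`, `aligned_b` (gapped strings
#'   of equal length), `score`, `identity_fraction`.
#' @export
needleman_wunsch <- function(seq_a, seq_b, matrix = blosum62(),
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0,
            gap_open >= 0, gap_extend >= 0)
  A <- strsplit(toupper(seq_a), "")[[1]]
  B <- strsplit(toupper(seq_b), "")[[1]]
  unknown <- setdiff(unique(c(A, B)), rownames(matrix))
  if (length(unknown) > 0) {
    stop("residue letter(s) not in substitution matrix: ",
         paste(unknown, collapse = ", "))
  }
  n <- length(A); m <- length(B)
  NEG <- -1e18
  # state matrices: M = match/mismatch, IX = gap in B (A residue vs gap),
  # IY = gap in A
  M <- matrix(NEG, n + 1, m + 1)
  IX <- matrix(NEG, n + 1, m + 1)
  IY <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    IX[i, 1] <- -gap_open - (i - 2) * gap_extend
  }
  for (j in 2:(m + 1)) {
    IY[1, j] <- -gap_open - (j - 2) * gap_extend
  }
  # pointers: 1 = from M, 2 = from IX, 3 = from IY
  pM <- matrix(0L, n + 1, m + 1)
  pX <- matrix(0L, n + 1, m + 1)
  pY <- matrix(0L, n + 1, m + 1)
  pick <- function(vals) which.max(vals)  # first max: M > IX > IY order
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- matrix[A[i - 1], B[j - 1]]
      vals <- c(M[i - 1, j - 1], IX[i - 1, j - 1], IY[i - 1, j - 1])
      k <- pick(vals)
      M[i, j] <- vals[k] + s
      pM[i, j] <- k
      vals <- c(M[i - 1, j] - gap_open, IX[i - 1, j] - gap_extend,
                IY[i - 1, j] - gap_open)
      k <- pick(vals)
      IX[i, j] <- vals[k]
      pX[i, j] <- k
      vals <- c(M[i, j - 1] - gap_open, IX[i, j - 1] - gap_open,
                IY[i, j - 1] - gap_extend)
      k <- pick(vals)
      IY[i, j] <- vals[k]
      pY[i, j] <- k
    }
  }
  # IX boundary column also needs pointers for traceback
  for (i in 2:(n + 1)) pX[i, 1] <- if (i == 2) 1L else 2L
  for (j in 2:(m + 1)) pY[1, j] <- if (j == 2) 1L else 3L
  finals <- c(M[n + 1, m + 1], IX[n + 1, m + 1], IY[n + 1, m + 1])
  state <- pick(finals)
  score <- finals[state]
  # traceback
  i <- n + 1; j <- m + 1
  ga <- character(0); gb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      ga <- c(A[i - 1], ga); gb <- c(B[j - 1], gb)
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ga <- c(A[i - 1], ga); gb <- c("-", gb)
      state <- pX[i, j]; i <- i - 1
    } else {
      ga <- c("-", ga); gb <- c(B[j - 1], gb)
      state <- pY[i, j]; j <- j - 1
    }
  }
  ident <- mean(ga == gb & ga != "-")
  structure(
    list(aligned_a = paste(ga, collapse = ""),
         aligned_b = paste(gb, collapse = ""),
         score = score,
         identity_fraction = ident),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score = ", x$score, ", identity = ",
      sprintf("%.1f%%", 100 * x$identity_fraction), "\n",
      x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}
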