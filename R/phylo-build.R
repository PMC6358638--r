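# Building the ultrametric analysis tree from fixed-length 16S V4 reads:
# primer-based truncation, uncorrected pairwise dissimilarity, and
# average-linkage (UPGMA) agglomerative clustering.

.iupac <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
            K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
            H = "[ACT]", V = "[ACG]", N = "[ACGTN]")

.primer_regex <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(chars, names(.iupac))
  if (length(bad))
    stop("primer contains non-IUPAC symbol(s): ", paste(bad, collapse = ""),
         call. = FALSE)
  paste0(.iupac[chars], collapse = "")
}

#' Truncate a 16S sequence to the amplified V4 region
#'
#' Locates the first match of the forward primer (IUPAC codes honoured) and
#' returns the `target_len` bases immediately following it — the region an
#' amplicon run with that primer pair would have produced. 250 bp is the
#' expected 515F/806R overlap.
#'
#' @param seq Nucleotide string.
#' @param fwd_primer Forward primer (IUPAC string), e.g. 515F
#'   `"GTGYCAGCMGCCGCGGTAA"`.
#' @param rev_primer Reverse primer; kept for interface symmetry, the
#'   truncation itself is length-based.
#' @param target_len Length of the retained region (default 250).
#' @return Character string of length `target_len`.
#' @export
truncate_to_region <- function(seq, fwd_primer, rev_primer = NULL,
                               target_len = 250) {
  seq <- toupper(seq)
  m <- regexpr(.primer_regex(fwd_primer), seq)
  if (m < 0)
    stop("region-not-found: forward primer has no match", call. = FALSE)
  start <- m + attr(m, "match.length")
  if (nchar(seq) - start + 1L < target_len)
    stop("truncation-error: fewer than ", target_len,
         " bases after the primer", call. = FALSE)
  substr(seq, start, start + target_len - 1L)
}

#' Uncorrected pairwise sequence dissimilarity
#'
#' Proportion of mismatching positions among positions where both bases
#' are unambiguous (A/C/G/T); positions with N or other ambiguity codes in
#' either sequence are excluded from both numerator and denominator.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings.
#' @return Dissimilarity in `[0, 1]` (`NA` if no comparable positions).
#' @export
pairwise_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length", call. = FALSE)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

#' All-pairs dissimilarity matrix for a sequence set
#'
#' @param seqs Named character vector of equal-length sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
seq_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  valid <- chars %in% c("A", "C", "G", "T")
  dim(valid) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid[i, ] & valid[j, ]
    d[i, j] <- d[j, i] <- if (any(ok)) mean(chars[i, ok] != chars[j, ok]) else NA_real_
  }
  d
}

#' Build an ultrametric tree by average-linkage agglomerative clustering
#'
#' UPGMA on a dissimilarity matrix. Each merge at height `h` places the
#' joined clusters so their cophenetic distance equals `h`; the result is
#' ultrametric by construction. Labels are processed in lexicographic
#' order so exact ties merge deterministically (smallest label first).
#'
#' @param d Symmetric nonnegative matrix (zero diagonal) or `dist` object.
#' @return An ultrametric `phylo` object.
#' @export
agglomerative_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be nonnegative with zero diagonal",
         call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)   # pendant heights = merge height / 2
  ape::reorder.phylo(phy, "cladewise")
}

#' Cophenetic (tree path) distance matrix
#'
#' @param tree A `phylo` object.
#' @return Symmetric matrix of tip-to-tip path-length distances.
#' @export
cophenetic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

#' Cophenetic distance between two tips
#'
#' Sum of branch lengths on the path between `tip_a` and `tip_b`; this is
#' the phylogenetic distance used by every downstream stage.
#'
#' @param tree A `phylo` object.
#' @param tip_a,tip_b Tip labels.
#' @return Nonnegative scalar.
#' @export
cophenetic_distance <- function(tree, tip_a, tip_b) {
  if (!all(c(tip_a, tip_b) %in% tree$tip.label))
    stop("unknown tip label", call. = FALSE)
  if (tip_a == tip_b) return(0)
  cm <- cophenetic_matrix(tree)
  cm[tip_a, tip_b]
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file (wrapped or single-line).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  vapply(as.character(x), function(s) toupper(paste(s, collapse = "")),
         character(1))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}
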