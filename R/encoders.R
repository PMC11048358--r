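#' Sequence encodings
#'
#' Two complementary numeric representations of an RNA window of length
#' `lambda` are used throughout the package:
#'
#' * **One-hot of k-nucleotides** (`scheme = "onehot"`): the window's
#'   `lambda - k + 1` overlapping k-mers are each expanded into a binary
#'   indicator block of size `4^k`, giving `4^k * (lambda - k + 1)`
#'   features laid out position-major. Every block contains exactly one 1.
#' * **K-mer frequency** (`scheme = "kmer"`): the `4^k` overlapping k-mer
#'   counts divided by `lambda - k + 1`, i.e. a probability vector.
#'
#' Columns follow lexicographic k-mer order with `A < C < G < U`.
#'
#' @name encodings
NULL

BASES <- c("A", "C", "G", "U")

#' Lexicographic index of a k-mer
#'
#' Maps a k-mer over `{A,C,G,U}` to its 0-based rank in lexicographic
#' order (`A < C < G < U`), i.e. its base-4 value with `A=0, C=1, G=2,
#' U=3`, most significant digit first.
#'
#' @param kmer Character vector of k-mers (all the same length).
#' @return Integer vector of 0-based indices in `[0, 4^k - 1]`.
#' @examples
#' kmer_index(c("A", "U"))   # 0 3
#' kmer_index("UUU")          # 63
#' @export
kmer_index <- function(kmer) {
  k <- unique(nchar(kmer))
  if (length(k) != 1) abort("All k-mers must have the same length.")
  codes <- match(strsplit(paste(kmer, collapse = ""), "")[[1]], BASES) - 1L
  if (anyNA(codes)) abort("k-mers must be over the alphabet {A,C,G,U}.")
  m <- matrix(codes, nrow = k)
  as.integer(colSums(m * 4^((k - 1):0)))
}

#' All k-mers in lexicographic order
#'
#' @param k k-mer length (1, 2 or 3 in the standard configuration).
#' @return Character vector of length `4^k`, ordered so that
#'   `kmer_index(kmers(k)) == 0:(4^k - 1)`.
#' @export
kmers <- function(k) {
  stopifnot(k >= 1)
  g <- expand.grid(rev(replicate(k, BASES, simplify = FALSE)),
                   stringsAsFactors = FALSE)
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
}

# n x (lambda - k + 1) matrix of 0-based k-mer indices per position
kmer_index_matrix <- function(seqs, k, lambda) {
  n <- length(seqs)
  codes <- matrix(
    match(strsplit(paste(seqs, collapse = ""), "")[[1]], BASES) - 1L,
    nrow = n, ncol = lambda, byrow = TRUE
  )
  npos <- lambda - k + 1
  idx <- matrix(0L, n, npos)
  for (j in seq_len(k)) {
    idx <- idx + codes[, j:(j + npos - 1), drop = FALSE] * 4L^(k - j)
  }
  idx
}

#' The standard set of six encodings
#'
#' One-hot and k-mer frequency for k = 1, 2, 3 — the six feature
#' representations whose pairing with the five base-classifier families
#' yields the 30-dimensional RNA profile.
#'
#' @return A tibble with columns `scheme`, `k` and `encoding` (a display
#'   name such as `"onehot3"`), one-hot first, k ascending within scheme.
#' @export
encoding_specs <- function() {
  tibble(
    scheme = rep(c("onehot", "kmer"), each = 3),
    k = rep(1:3, 2),
    encoding = paste0(rep(c("onehot", "kmer"), each = 3), rep(1:3, 2))
  )
}

#' Encode RNA windows as a numeric feature matrix
#'
#' @param x A windows table (see [rna_windows()]).
#' @param scheme `"onehot"` or `"kmer"` (see [encodings]).
#' @param k k-mer length, `1 <= k <= lambda`.
#' @return A numeric matrix with one row per window and named columns
#'   (`pos<p>_<kmer>` for one-hot, the k-mer itself for frequencies),
#'   carrying attributes `scheme`, `k` and `lambda`.
#' @examples
#' w <- rna_windows(tibble::tibble(id = "s", sequence = "ACGUUUGCA"),
#'                  center_u = "off")
#' dim(encode_windows(w, "onehot", 2))   # 1 x 128
#' rowSums(encode_windows(w, "kmer", 2)) # 1
#' @export
encode_windows <- function(x, scheme = c("onehot", "kmer"), k = 1) {
  scheme <- match.arg(scheme)
  lambda <- window_length(x)
  if (is.na(lambda)) abort("Cannot encode an empty windows table.")
  if (k < 1 || k > lambda) {
    abort(sprintf("k must satisfy 1 <= k <= lambda (= %d); got %d.", lambda, k))
  }
  n <- nrow(x)
  npos <- lambda - k + 1
  idx <- kmer_index_matrix(x$sequence, k, lambda)
  if (scheme == "onehot") {
    m <- matrix(0, n, 4^k * npos)
    # column of the 1 in block p is (p-1)*4^k + idx + 1
    cols <- sweep(idx + 1L, 2, (seq_len(npos) - 1L) * 4L^k, "+")
    m[cbind(rep(seq_len(n), npos), as.vector(cols))] <- 1
    colnames(m) <- paste0(
      "pos", rep(seq_len(npos), each = 4^k), "_", rep(kmers(k), npos)
    )
  } else {
    m <- matrix(0, n, 4^k)
    for (i in seq_len(n)) {
      tab <- tabulate(idx[i, ] + 1L, nbins = 4^k)
      m[i, ] <- tab / npos
    }
    colnames(m) <- kmers(k)
  }
  structure(m, scheme = scheme, k = as.integer(k), lambda = lambda)
}

#' Dimension of an encoding
#'
#' `4^k * (lambda - k + 1)` features for one-hot, `4^k` for k-mer
#' frequencies.
#'
#' @param scheme `"onehot"` or `"kmer"`.
#' @param k k-mer length.
#' @param lambda Window length (ignored for `"kmer"`).
#' @return Integer feature count.
#' @export
encoding_dim <- function(scheme, k, lambda = NULL) {
  if (scheme == "onehot") {
    stopifnot(!is.null(lambda))
    as.integer(4^k * (lambda - k + 1))
  } else {
    as.integer(4^k)
  }
}

#' Export a feature matrix as headered TSV
#'
#' @param m A matrix from [encode_windows()].
#' @param path Output path.
#' @param ids Optional row identifiers written as a leading `id` column.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(m, path, ids = NULL) {
  df <- as.data.frame(m)
  if (!is.null(ids)) df <- cbind(id = ids, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
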