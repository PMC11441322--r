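#' Embedder contracts
#'
#' An embedder is a deterministic map from a batch of texts to fixed-length
#' numeric vectors, represented as a `kg_embedder` object holding a `name`,
#' a `dimension` and an `embed` function returning one row per input text.
#' Vectors are L2-normalized at embed time, so cosine similarity reduces to a
#' dot product everywhere downstream. Production sentence-transformer models
#' (e.g. a MiniLM for disease names and a biomedical BERT for context
#' sentences) plug in through [embedder()]; tests and offline runs use the
#' [reference_embedder()].
#'
#' @param name Embedder name stamp.
#' @param dimension Embedding dimension.
#' @param embed_fn Function taking a character vector and returning a numeric
#'   matrix with `length(texts)` rows and `dimension` columns. Rows are
#'   re-normalized defensively; all-zero rows are left as zero vectors.
#' @return A `kg_embedder`.
#' @export
embedder <- function(name, dimension, embed_fn) {
  stopifnot(is.character(name), length(name) == 1,
    is.numeric(dimension), length(dimension) == 1, dimension >= 1,
    is.function(embed_fn))
  structure(
    list(name = name, dimension = as.integer(dimension), embed_fn = embed_fn),
    class = "kg_embedder"
  )
}

#' @export
print.kg_embedder <- function(x, ...) {
  cat(sprintf("<kg_embedder> %s (%d dimensions)\n", x$name, x$dimension))
  invisible(x)
}

#' Embed a batch of texts
#'
#' @param emb A [embedder()].
#' @param texts Character vector.
#' @return Numeric matrix, one unit-norm row per text (all-zero rows for
#'   texts the embedder maps to the zero vector).
#' @export
embed_texts <- function(emb, texts) {
  stopifnot(inherits(emb, "kg_embedder"))
  if (length(texts) == 0) {
    return(matrix(numeric(), nrow = 0, ncol = emb$dimension))
  }
  m <- emb$embed_fn(as.character(texts))
  m <- matrix(as.numeric(m), nrow = length(texts), ncol = emb$dimension)
  l2_normalize_rows(m)
}

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Deterministic character-trigram reference embedder
#'
#' A lightweight, fully deterministic sentence embedder used for tests,
#' examples and offline runs: the text is case-folded and NFC-normalized, its
#' multiset of character trigrams is hashed into a fixed-dimension count
#' vector, and the vector is L2-normalized. Texts shorter than three
#' characters contribute themselves as a single gram; the empty string maps
#' to the zero vector, whose cosine similarity against anything is defined
#' as 0.
#'
#' Because of the case-folding step this embedder is exactly
#' case-insensitive, which is what makes semantic retrieval provably
#' invariant under lower-casing perturbations of the input (in contrast to
#' exact-string matching).
#'
#' @param dimension Number of hash buckets (default 256).
#' @return A [embedder()].
#' @examples
#' emb <- reference_embedder()
#' v <- embed_texts(emb, c("hypertension", "HYPERTENSION"))
#' identical(v[1, ], v[2, ])
#' @export
reference_embedder <- function(dimension = 256L) {
  dimension <- as.integer(dimension)
  embedder(
    name = sprintf("trigram-hash-%d", dimension),
    dimension = dimension,
    embed_fn = function(texts) {
      norm <- stringi::stri_trans_nfc(stringr::str_to_lower(texts))
      m <- matrix(0, nrow = length(texts), ncol = dimension)
      for (i in seq_along(norm)) {
        cp <- utf8ToInt(norm[i])
        n <- length(cp)
        if (n == 0) next
        if (n < 3) {
          idx <- poly_hash(list(cp), dimension)
        } else {
          grams <- map(seq_len(n - 2L), function(j) cp[j:(j + 2L)])
          idx <- poly_hash(grams, dimension)
        }
        tab <- tabulate(idx, nbins = dimension)
        m[i, ] <- tab
      }
      m
    }
  )
}

# Polynomial rolling hash of each codepoint vector, modulo the dimension.
# Fixed base 31 keeps the value integer-exact well inside double precision
# for 3-codepoint grams, so results are identical across platforms.
poly_hash <- function(grams, dimension) {
  map_int(grams, function(cp) {
    h <- 0
    for (c in cp) h <- (h * 31 + c) %% dimension
    as.integer(h) + 1L
  })
}

#' Cosine similarity between a query vector and index rows
#'
#' Rows and query are unit-norm (or zero), so this is a plain matrix-vector
#' product; any zero vector yields similarity 0.
#' @param m Numeric matrix of unit-norm rows.
#' @param v Unit-norm (or zero) numeric vector.
#' @return Numeric vector of similarities in `[-1, 1]`.
#' @keywords internal
cosine_against <- function(m, v) {
  if (nrow(m) == 0) return(numeric())
  as.numeric(m %*% v)
}
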