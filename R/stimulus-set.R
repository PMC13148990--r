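#' Generate a synthetic face/object stimulus set
#'
#' Draws stimulus embeddings emulating the structure of deep-network image
#' embeddings of faces and non-face objects: a zero-mean Gaussian cloud with
#' mildly decaying per-dimension variance, with the face rows additionally
#' shifted by `category_offset` so that faces occupy one quadrant of the first
#' two embedding directions (the "detection" direction a general-object space
#' picks up as its leading principal components).
#'
#' @param n_face,n_object Number of face / object stimuli (each >= 2).
#' @param D Embedding dimensionality (>= 2).
#' @param category_offset Numeric vector of length `D` (or a scalar, recycled
#'   with zeros beyond the first two dimensions when `NULL`): the displacement
#'   added to every face embedding. The default shifts faces by +3 along the
#'   first and +1.5 along the second embedding direction.
#' @param sd_decay Per-dimension geometric decay of the embedding standard
#'   deviation: dimension j has s.d. `sd_decay^(j-1)`. A value below 1 gives
#'   the embedding an ordered variance spectrum so that a PCA feature space
#'   aligns (up to sign) with the generating coordinates.
#' @param face_compactness Scale (< 1 shrinks) of the face rows' deviations
#'   along the offset (detection) dimensions: faces form a compact cluster
#'   in the leading dimensions of object space, unlike the broad object
#'   cloud.
#' @param seed Integer seed; identical seeds give bit-identical sets.
#'
#' @return A `stimulus_set`: list with `embeddings` (stimuli x D matrix),
#'   `category` (factor with levels `face`, `object`) and `ids` (unique
#'   character ids, faces first).
#' @export
make_stimulus_set <- function(n_face, n_object, D = 60, category_offset = NULL,
                              sd_decay = 0.94, face_compactness = 1, seed = 1) {
  stopifnot(n_face >= 2, n_object >= 2, D >= 2)
  if (is.null(category_offset)) {
    category_offset <- c(3, 1.5, rep(0, D - 2))
  } else if (length(category_offset) == 1) {
    category_offset <- c(category_offset, rep(0, D - 1))
  }
  if (length(category_offset) != D || any(!is.finite(category_offset))) {
    abort("`category_offset` must be finite and of length D.")
  }
  n <- n_face + n_object
  sds <- sd_decay^(seq_len(D) - 1)
  emb <- with_seed(seed, {
    matrix(rnorm(n * D), n, D) %*% diag(sds, D)
  })
  off_dims <- which(category_offset != 0)
  if (face_compactness != 1 && length(off_dims) > 0) {
    emb[seq_len(n_face), off_dims] <- face_compactness *
      emb[seq_len(n_face), off_dims, drop = FALSE]
  }
  emb[seq_len(n_face), ] <- sweep(emb[seq_len(n_face), , drop = FALSE], 2,
                                  category_offset, "+")
  ids <- c(sprintf("face_%04d", seq_len(n_face)),
           sprintf("obj_%04d", seq_len(n_object)))
  structure(
    list(
      embeddings = `rownames<-`(emb, ids),
      category = factor(rep(c("face", "object"), c(n_face, n_object)),
                        levels = c("face", "object")),
      ids = ids
    ),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli (%d face, %d object), D = %d\n",
              length(x$ids), sum(x$category == "face"),
              sum(x$category == "object"), ncol(x$embeddings)))
  invisible(x)
}

#' @rdname make_stimulus_set
#' @param x A `stimulus_set`.
#' @param ... Unused.
#' @method tidy stimulus_set
#' @export
tidy.stimulus_set <- function(x, ...) {
  tibble::tibble(
    id = x$ids,
    category = as.character(x$category),
    embedding = purrr::map(seq_along(x$ids), function(i) x$embeddings[i, ])
  )
}

#' Construct a stimulus set from given embeddings
#'
#' Low-level constructor for custom stimulus sets (e.g. hand-crafted feature
#' configurations in analyses or tests).
#'
#' @param embeddings stimuli x D numeric matrix.
#' @param category Per-stimulus labels in `{face, object}`.
#' @param ids Unique stimulus identifiers.
#' @return A `stimulus_set`.
#' @export
stimulus_set <- function(embeddings, category,
                         ids = rownames(embeddings)) {
  embeddings <- as.matrix(embeddings)
  if (is.null(ids)) ids <- sprintf("stim_%04d", seq_len(nrow(embeddings)))
  if (anyDuplicated(ids)) abort("stimulus ids must be unique")
  if (length(category) != nrow(embeddings)) abort("category length mismatch")
  structure(
    list(embeddings = `rownames<-`(embeddings, ids),
         category = factor(as.character(category), levels = c("face", "object")),
         ids = ids),
    class = "stimulus_set"
  )
}
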