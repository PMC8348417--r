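# Dimensionality reduction: PCA implemented from the eigendecomposition of
# the covariance matrix, plus a pluggable-backend contract for nonlinear
# embeddings (t-SNE / UMAP), whose internals are deliberately delegated.

#' Principal-component projection
#'
#' Centers the columns of `X`, eigendecomposes the covariance matrix and
#' projects onto the top-`k` eigenvectors (computed directly, not delegated
#' to a PCA routine). Component variances are returned in non-increasing
#' order.
#'
#' @param X Numeric matrix (rows = observations).
#' @param k Number of components, `k <= ncol(X)`.
#' @return `n x k` score matrix with attributes `rotation` (loadings),
#'   `center`, and `component_variance`.
#' @export
pca_project <- function(X, k = 2) {
  X <- as.matrix(X)
  if (k > ncol(X)) {
    abort(sprintf("k = %d exceeds the %d available columns.", k, ncol(X)))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  rot <- ev$vectors[, seq_len(k), drop = FALSE]
  structure(Xc %*% rot,
            rotation = rot, center = ctr,
            component_variance = pmax(ev$values[seq_len(k)], 0))
}

the_embed_backends <- new.env(parent = emptyenv())

#' Pluggable nonlinear embedding backends
#'
#' `embed_features()` maps a feature matrix to a `k`-dimensional embedding
#' through a registered backend. The backend contract: a function
#' `f(X, k, seed, ...)` returning an `nrow(X) x k` numeric matrix,
#' deterministic for a fixed `seed`. No t-SNE or UMAP implementation ships
#' with this package; register one with `register_embedding_backend()`
#' (e.g. wrapping `Rtsne::Rtsne` or `uwot::umap` where available). Calling
#' an unregistered method raises a clear unavailable-method error.
#'
#' @param X Numeric matrix (rows = observations).
#' @param method `"tsne"` or `"umap"`.
#' @param k Embedding dimension (default 2).
#' @param seed Integer seed forwarded to the backend.
#' @param ... Passed through to the backend.
#' @return `n x k` embedding matrix.
#' @export
embed_features <- function(X, method = c("tsne", "umap"), k = 2, seed = 1L,
                           ...) {
  method <- match.arg(method)
  backend <- the_embed_backends[[method]]
  if (is.null(backend)) {
    abort(sprintf(
      paste("No '%s' embedding backend is registered and none is bundled;",
            "register one with register_embedding_backend(\"%s\", fun)."),
      method, method))
  }
  out <- backend(as.matrix(X), k = k, seed = seed, ...)
  if (!is.matrix(out) || nrow(out) != nrow(X) || ncol(out) != k) {
    abort(sprintf("Backend '%s' violated the contract: expected a %d x %d matrix.",
                  method, nrow(X), k))
  }
  out
}

#' @rdname embed_features
#' @param fun Backend function `f(X, k, seed, ...)`.
#' @export
register_embedding_backend <- function(method = c("tsne", "umap"), fun) {
  method <- match.arg(method)
  stopifnot(is.function(fun))
  assign(method, fun, envir = the_embed_backends)
  invisible(method)
}

#' @rdname embed_features
#' @export
list_embedding_backends <- function() {
  ls(the_embed_backends)
}

#' @rdname embed_features
#' @export
clear_embedding_backends <- function() {
  rm(list = ls(the_embed_backends), envir = the_embed_backends)
  invisible(NULL)
}
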