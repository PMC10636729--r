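# Inverse-Wishart draw: X ~ IW(scale, df) via X = W^-1, W ~ Wishart(df, scale^-1).
# E[X] = scale / (df - p - 1) for df > p + 1. Fractional df supported.
rinvwishart <- function(scale, df) {
  p <- nrow(scale)
  if (df <= p - 1) stop("inverse-Wishart degrees of freedom must exceed dim - 1", call. = FALSE)
  if (p == 1L) return(scale / rchisq(1L, df))
  W <- stats::rWishart(1L, df, chol2inv(chol(scale)))[, , 1L]
  chol2inv(chol(W))
}

#' One Gibbs draw of a random-effect covariance matrix
#'
#' Samples from the conditional inverse-Wishart distribution of a covariance
#' matrix given the accumulated outer product of its effect vectors, under
#' an inverse-Wishart prior. An optional symmetric mask fixes selected
#' off-diagonal elements to exactly zero: the unmasked entries must then
#' form disconnected diagonal blocks, each of which is sampled from its own
#' conditional inverse-Wishart, and the masked cross-block elements are
#' returned as exact zeros.
#'
#' @param crossprod_matrix Sum over levels of the outer products of effect
#'   vectors (symmetric positive semidefinite).
#' @param n_levels Number of effect vectors entering `crossprod_matrix`.
#' @param prior `list(V, nu)`: inverse-Wishart scale matrix and degrees of
#'   freedom. The conditional is `IW(V + crossprod, nu + n_levels)`.
#' @param mask Optional symmetric logical matrix, `TRUE` where an element is
#'   fixed to zero. Diagonal entries may not be masked.
#'
#' @return A covariance matrix draw with masked elements exactly zero.
#' @export
gibbs_update_covariance <- function(crossprod_matrix, n_levels, prior, mask = NULL) {
  p <- nrow(crossprod_matrix)
  if (is.null(mask)) mask <- matrix(FALSE, p, p)
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric", call. = FALSE)
  if (any(diag(mask))) stop("diagonal elements may not be masked to zero", call. = FALSE)
  blocks <- mask_blocks(!mask)
  out <- matrix(0, p, p, dimnames = dimnames(crossprod_matrix))
  for (b in blocks) {
    pb <- length(b)
    if (prior$nu <= pb - 1) {
      stop(sprintf("prior degrees of freedom %.3f below minimum for a %d-dimensional block",
                   prior$nu, pb), call. = FALSE)
    }
    Vb <- if (is.matrix(prior$V)) prior$V[b, b, drop = FALSE] else diag(prior$V, pb)
    out[b, b] <- rinvwishart(Vb + crossprod_matrix[b, b, drop = FALSE],
                             prior$nu + n_levels)
  }
  out
}

# Connected components of the adjacency graph of free (unmasked) elements.
mask_blocks <- function(free) {
  p <- nrow(free)
  seen <- rep(FALSE, p)
  blocks <- list()
  for (i in seq_len(p)) {
    if (seen[i]) next
    comp <- i
    repeat {
      nbr <- which(apply(free[comp, , drop = FALSE], 2, any))
      nxt <- setdiff(nbr, comp)
      if (!length(nxt)) break
      comp <- sort(c(comp, nxt))
    }
    seen[comp] <- TRUE
    blocks[[length(blocks) + 1L]] <- comp
  }
  blocks
}
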