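#' Permutation scheme
#'
#' Describes how observations may be rearranged under the null: the number of
#' permutations, optional exchangeability blocks (e.g. runs of one subject in
#' a paired drug on/off design) and whether shuffling is restricted to within
#' blocks.
#'
#' @param n_perm number of permutations, identity included.
#' @param blocks optional vector assigning each observation to a block.
#' @param within_block_only if \code{TRUE}, observations are only permuted
#'   within their block (paired/within-subject designs).
#' @param seed optional RNG seed for Monte-Carlo permutation draws.
#' @return a list of class \code{permutation_scheme}.
#' @export
permutation_scheme <- function(n_perm, blocks = NULL,
                               within_block_only = FALSE, seed = NULL) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  if (within_block_only && is.null(blocks))
    stop("within-block permutation requires block labels")
  structure(list(n_perm = as.integer(n_perm), blocks = blocks,
                 within_block_only = isTRUE(within_block_only), seed = seed),
            class = "permutation_scheme")
}

# all permutations of a vector (small n only)
.all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(list(v))
  out <- list()
  for (i in seq_len(n))
    out <- c(out, lapply(.all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# enumerate two-group label reassignments as row-index permutations;
# data rows are permuted against a fixed design, so the induced assignment
# is the set of rows landing in the smaller group's design positions
.enumerate_two_group <- function(groups, n_perm) {
  lev <- unique(groups)
  g1 <- which(groups == lev[1L])
  g2 <- which(groups == lev[2L])
  n <- length(groups)
  pos_small <- if (length(g1) <= length(g2)) g1 else g2
  pos_other <- setdiff(seq_len(n), pos_small)
  n_distinct <- choose(n, length(pos_small))
  if (n_distinct > n_perm) return(NULL)
  subsets <- utils::combn(n, length(pos_small))
  perms <- matrix(NA_integer_, ncol(subsets), n)
  for (b in seq_len(ncol(subsets))) {
    rows_small <- subsets[, b]
    p <- integer(n)
    p[pos_small] <- rows_small
    p[pos_other] <- setdiff(seq_len(n), rows_small)
    perms[b, ] <- p
  }
  ident <- which(apply(perms, 1L, identical, y = seq_len(n)))
  rbind(perms[ident, ], perms[-ident, , drop = FALSE])
}

#' Generate the permutation stream
#'
#' Produces a matrix of row-index permutations, one permutation per row, with
#' the identity always first. Distinct rearrangements are fully enumerated
#' when their number does not exceed \code{n_perm} (two-group label
#' reassignments when a two-group design is supplied; within-block shuffles
#' when blocks are small); otherwise Monte-Carlo draws are used.
#'
#' @param n_obs number of observations.
#' @param scheme a \code{\link{permutation_scheme}}.
#' @param groups optional group label per observation; with exactly two
#'   levels, enables enumeration of distinct label reassignments.
#' @return integer matrix, permutations x observations; attribute
#'   \code{enumerated} records whether the stream is exhaustive.
#' @export
make_permutations <- function(n_obs, scheme, groups = NULL) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  n_perm <- scheme$n_perm
  if (scheme$within_block_only) {
    blocks <- scheme$blocks
    if (length(blocks) != n_obs)
      stop("blocks must label every observation")
    idx <- split(seq_len(n_obs), blocks)
    sizes <- lengths(idx)
    if (any(sizes < 2L))
      stop("within-block permutation requires every block to have >= 2 ",
           "observations (no exchangeability in blocks of size 1)")
    n_distinct <- prod(factorial(sizes))
    if (n_distinct <= n_perm) {
      per_block <- lapply(idx, .all_perms)
      grid <- expand.grid(lapply(per_block, seq_along))
      perms <- matrix(NA_integer_, nrow(grid), n_obs)
      for (b in seq_len(nrow(grid))) {
        p <- seq_len(n_obs)
        for (j in seq_along(idx))
          p[idx[[j]]] <- per_block[[j]][[grid[b, j]]]
        perms[b, ] <- p
      }
      ident <- which(apply(perms, 1L, identical, y = seq_len(n_obs)))
      perms <- rbind(perms[ident, ], perms[-ident, , drop = FALSE])
      attr(perms, "enumerated") <- TRUE
      return(perms)
    }
    perms <- with_seed(scheme$seed, {
      t(vapply(seq_len(n_perm), function(b) {
        if (b == 1L) return(seq_len(n_obs))
        p <- seq_len(n_obs)
        for (j in seq_along(idx)) {
          ii <- idx[[j]]
          p[ii] <- ii[sample.int(length(ii))]
        }
        p
      }, integer(n_obs)))
    })
    attr(perms, "enumerated") <- FALSE
    return(perms)
  }
  if (!is.null(groups) && length(unique(groups)) == 2L) {
    perms <- .enumerate_two_group(groups, n_perm)
    if (!is.null(perms)) {
      attr(perms, "enumerated") <- TRUE
      return(perms)
    }
  }
  perms <- with_seed(scheme$seed, {
    t(vapply(seq_len(n_perm), function(b) {
      if (b == 1L) seq_len(n_obs) else sample.int(n_obs)
    }, integer(n_obs)))
  })
  attr(perms, "enumerated") <- FALSE
  perms
}

#' Family-aware permutations for related subjects
#'
#' Restricted exchangeability for populations with family structure: whole
#' families may swap positions only with families of the same size, and
#' subjects shuffle freely within their family. The identity is always the
#' first permutation.
#'
#' @param family vector of family ids, one per subject.
#' @param n_perm number of permutations, identity included.
#' @param seed optional RNG seed.
#' @return integer matrix, permutations x subjects, of row indices.
#' @export
make_family_permutations <- function(family, n_perm, seed = NULL) {
  family <- as.character(family)
  n <- length(family)
  fams <- split(seq_len(n), family)
  sizes <- lengths(fams)
  by_size <- split(fams, sizes)
  with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      p <- integer(n)
      if (b == 1L) return(seq_len(n))
      for (cls in by_size) {
        ord <- sample.int(length(cls))
        slots <- unlist(cls, use.names = FALSE)
        members <- unlist(lapply(cls[ord], function(ix)
          if (length(ix) == 1L) ix else ix[sample.int(length(ix))]),
          use.names = FALSE)
        p[slots] <- members
      }
      p
    }, integer(n)))
  })
}
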