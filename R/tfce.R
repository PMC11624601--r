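#' TFCE parameters
#'
#' Threshold-free cluster enhancement integrates cluster extent^E x height^H
#' over thresholds from `h0` in steps of `dh`. Defaults follow standard TFCE
#' practice for E and H with a fine step for a closer approximation of the
#' integral.
#'
#' @param E extent exponent.
#' @param H height exponent.
#' @param h0 starting threshold.
#' @param dh integration step.
#' @param n_perm number of permutations.
#' @param two_sided enhance positive and negative statistics separately.
#' @param p_type `"max"` (max-TFCE-across-map null, family-wise corrected) or
#'   `"pointwise"` (per-point exceedance proportion).
#' @param alpha significance level for the cluster mask.
#' @return list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, h0 = 0, dh = 0.4, n_perm = 5000L,
                        two_sided = TRUE, p_type = c("max", "pointwise"),
                        alpha = 0.05) {
  stopifnot(dh > 0, n_perm >= 1)
  structure(list(E = E, H = H, h0 = h0, dh = dh, n_perm = as.integer(n_perm),
                 two_sided = two_sided, p_type = match.arg(p_type),
                 alpha = alpha), class = "tfce_params")
}

#' TFCE enhancement of a vertex-by-time statistic map
#'
#' Each supra-threshold (`stat >= h`) spatiotemporal connected component of
#' extent `e` contributes `e^E * h^H * dh` to every member point, summed over
#' thresholds `h0 + dh, h0 + 2*dh, ...` up to the map maximum (with a final
#' partial step to the maximum). With `two_sided`, positive and negative parts
#' are enhanced separately and recombined with sign.
#'
#' @param stat_map numeric matrix, vertices x time.
#' @param edges 2-column integer matrix of 1-based spatial edges among the
#'   rows of `stat_map`.
#' @param params a [tfce_params()].
#' @return enhanced map, same dimensions.
#' @export
tfce_enhance <- function(stat_map, edges, params = tfce_params()) {
  stopifnot(is.matrix(stat_map), all(is.finite(stat_map)))
  if (length(stat_map) == 0L) return(stat_map)
  cpp_tfce(stat_map, edges_c(edges), params$E, params$H, params$h0, params$dh,
           params$two_sided)
}

# 1-based R edges -> 0-based integer matrix for C++
edges_c <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(matrix(integer(0), 0, 2))
  storage.mode(edges) <- "integer"
  edges - 1L
}

#' Spatiotemporal connected components
#'
#' Components of a boolean vertex-by-time mask under the edge set
#' \{spatial neighbour, same time\} plus \{same vertex, adjacent time\}.
#'
#' @param mask logical matrix, vertices x time.
#' @param edges 2-column 1-based spatial edge matrix.
#' @return integer label matrix (0 = background).
#' @export
connected_components <- function(mask, edges) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  cpp_connected_components(mask, edges_c(edges))
}

# subset the spatial edges to a vertex set, remapped to local indices
local_edges <- function(space, vs) {
  keep <- space$edges[, 1] %in% vs & space$edges[, 2] %in% vs
  e <- space$edges[keep, , drop = FALSE]
  matrix(match(e, vs), ncol = 2)
}

assemble_result <- function(space, per_hemi, params, n_perm) {
  V <- space$n; Tn <- ncol(per_hemi[[1]]$stat)
  stat <- tfce <- p <- matrix(NA_real_, V, Tn)
  for (h in names(per_hemi)) {
    vs <- which(space$hemi == h)
    stat[vs, ] <- per_hemi[[h]]$stat
    tfce[vs, ] <- per_hemi[[h]]$tfce
    p[vs, ] <- per_hemi[[h]]$p
  }
  sig <- p < params$alpha
  clusters <- connected_components(sig, space$edges)
  structure(list(stat_map = stat, tfce_map = tfce, p_map = p, sig_mask = sig,
                 clusters = clusters, space = space, params = params,
                 n_perm = n_perm,
                 max_null = lapply(per_hemi, `[[`, "max_null")),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  ns <- sum(x$sig_mask)
  nc <- max(x$clusters)
  cat(sprintf("<tfce_result> %d x %d map, %d significant points (alpha = %g) in %d cluster(s), %d permutations\n",
              nrow(x$p_map), ncol(x$p_map), ns, x$params$alpha, nc, x$n_perm))
  invisible(x)
}

# corrected p-values; under "max" the null is the max |TFCE| per permutation
# over BOTH hemispheres (clusters never span hemispheres, but the correction
# family is the whole analysed map), enabled by the shared permutation
# schedule. Under "pointwise" each point uses its own exceedance proportion.
add_pvalues <- function(per_hemi, params, n_perm) {
  max_null <- Reduce(pmax, lapply(per_hemi, `[[`, "max_null"))
  srt <- sort(max_null)
  for (h in names(per_hemi)) {
    fit <- per_hemi[[h]]
    if (params$p_type == "max") {
      tf <- abs(as.vector(fit$tfce))
      # permutations with max |TFCE| >= observed, via binary search
      cnt <- n_perm - findInterval(tf - 1e-12, srt)
      p <- (1 + cnt) / (n_perm + 1)
    } else {
      p <- (1 + fit$exceed) / (n_perm + 1)
    }
    per_hemi[[h]]$p <- matrix(p, nrow(fit$tfce), ncol(fit$tfce))
    per_hemi[[h]]$max_null <- max_null
  }
  per_hemi
}

#' One-sample spatiotemporal TFCE permutation test
#'
#' Tests whether per-subject difference maps (test minus control responses)
#' deviate from zero: the statistic is the one-sample t across subjects and
#' the null is built by random sign flips of whole-subject maps. Hemispheres
#' are processed disjointly with a shared permutation schedule; when the
#' requested number of permutations reaches the number of unique sign
#' patterns, all `2^n` flips are enumerated exhaustively. Corrected p-values
#' use the max-TFCE null distribution over the whole analysed map by default
#' (clusters are formed per hemisphere; the correction family is both).
#'
#' @param diffs array `[subject, vertex, time]` of difference maps.
#' @param space the `source_space`.
#' @param params a [tfce_params()].
#' @return a `tfce_result`.
#' @export
one_sample_tfce_test <- function(diffs, space, params = tfce_params()) {
  stopifnot(length(dim(diffs)) == 3L, dim(diffs)[2] == space$n)
  n <- dim(diffs)[1]
  if (n < 2L) stop("need at least 2 subjects")
  exhaustive <- n <= 30 && 2^n <= params$n_perm
  signs <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(1L, -1L)), n)))
  } else {
    matrix(sample(c(1L, -1L), n * params$n_perm, replace = TRUE), n)
  }
  if (exhaustive) signs <- t(signs)
  storage.mode(signs) <- "integer"
  n_perm <- ncol(signs)
  per_hemi <- list()
  for (h in c("L", "R")) {
    vs <- which(space$hemi == h)
    X <- matrix(aperm(diffs[, vs, , drop = FALSE], c(1, 2, 3)),
                nrow = n)                            # n x (V*T), v fastest
    per_hemi[[h]] <- cpp_perm_one_sample(X, signs, length(vs), dim(diffs)[3],
                                         edges_c(local_edges(space, vs)),
                                         params$E, params$H, params$h0,
                                         params$dh, params$two_sided)
  }
  assemble_result(space, add_pvalues(per_hemi, params, n_perm), params, n_perm)
}

#' Two-sample spatiotemporal TFCE permutation test
#'
#' Compares differential responses between two groups: the statistic is the
#' two-sided two-sample t (group A minus group B) and the null is built by
#' shuffling group labels. Otherwise as [one_sample_tfce_test()].
#'
#' @param diffs_a,diffs_b arrays `[subject, vertex, time]` per group.
#' @param space the `source_space`.
#' @param params a [tfce_params()].
#' @return a `tfce_result`.
#' @export
two_sample_tfce_test <- function(diffs_a, diffs_b, space,
                                 params = tfce_params()) {
  stopifnot(dim(diffs_a)[2] == space$n, dim(diffs_b)[2] == space$n,
            dim(diffs_a)[3] == dim(diffs_b)[3])
  na <- dim(diffs_a)[1]; nb <- dim(diffs_b)[1]
  if (na < 2L || nb < 2L) stop("need at least 2 subjects per group")
  n <- na + nb
  grp <- c(rep(0L, na), rep(1L, nb))
  perms <- vapply(seq_len(params$n_perm), function(k) sample(grp),
                  integer(n))
  per_hemi <- list()
  for (h in c("L", "R")) {
    vs <- which(space$hemi == h)
    X <- rbind(matrix(diffs_a[, vs, , drop = FALSE], nrow = na),
               matrix(diffs_b[, vs, , drop = FALSE], nrow = nb))
    per_hemi[[h]] <- cpp_perm_two_sample(X, grp, perms, length(vs),
                                         dim(diffs_a)[3],
                                         edges_c(local_edges(space, vs)),
                                         params$E, params$H, params$h0,
                                         params$dh, params$two_sided)
  }
  assemble_result(space, add_pvalues(per_hemi, params, params$n_perm),
                  params, params$n_perm)
}
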