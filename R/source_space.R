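#' Build a surrogate cortical source space
#'
#' A planar-grid graph per hemisphere stands in for the resampled cortical
#' mesh: vertices carry a hemisphere label and a region label. Contiguous
#' patches for the primary auditory cortex (A1), the parabelt area A4 and the
#' posterior insular auditory region (pINS) sit inside an "STG+" band of
#' auditory labels; the remaining vertices are outside STG+. No edges cross
#' hemispheres, so spatial clusters can never merge across them.
#'
#' @param n_per_hemi vertices per hemisphere (>= 50).
#' @return an object of class `source_space`: `n` (total vertices), `edges`
#'   (2-column matrix of undirected spatial edges), `hemi` (character vector
#'   `"L"`/`"R"`), `region` (character: `"A1"`, `"A4"`, `"pINS"`, `"STG+"`,
#'   `"outside"`), `stg` (logical STG+ mask = union of the auditory labels).
#' @export
make_source_space <- function(n_per_hemi = 50L) {
  n_per_hemi <- as.integer(n_per_hemi)
  if (n_per_hemi < 50L) stop("need at least 50 vertices per hemisphere")
  rows <- floor(sqrt(n_per_hemi))
  while (n_per_hemi %% rows != 0L) rows <- rows - 1L
  cols <- n_per_hemi %/% rows
  if (rows < 3L || cols < 5L)
    stop("n_per_hemi = ", n_per_hemi, " does not factor into a usable grid")

  # vertex v = (col - 1) * rows + row, per hemisphere
  grid_edges <- function(offset) {
    e <- list()
    for (cc in seq_len(cols)) for (rr in seq_len(rows)) {
      v <- (cc - 1L) * rows + rr
      if (rr < rows) e[[length(e) + 1L]] <- c(v, v + 1L)
      if (cc < cols) e[[length(e) + 1L]] <- c(v, v + rows)
    }
    do.call(rbind, e) + offset
  }
  edges <- rbind(grid_edges(0L), grid_edges(n_per_hemi))

  # region layout by column band: outside | A1 | A4 | pINS | STG+ remainder.
  # The interior band (all but the first and last column) is STG+.
  region <- rep("outside", n_per_hemi)
  col_of <- rep(seq_len(cols), each = rows)
  inner <- col_of > 1L & col_of < cols
  region[inner] <- "STG+"
  band <- function(lo, hi) inner & col_of >= lo & col_of <= hi
  third <- max(1L, (cols - 2L) %/% 3L)
  a1 <- band(2L, 1L + third)
  a4 <- band(2L + third, 1L + 2L * third)
  pins <- band(2L + 2L * third, 1L + 3L * third)
  region[a1] <- "A1"; region[a4] <- "A4"; region[pins] <- "pINS"
  if (!all(c("A1", "A4", "pINS", "STG+", "outside") %in% region))
    stop("grid too small to host all region patches")

  region <- rep(region, 2L)
  hemi <- rep(c("L", "R"), each = n_per_hemi)
  structure(list(
    n = 2L * n_per_hemi, n_per_hemi = n_per_hemi,
    grid = c(rows = rows, cols = cols),
    edges = edges, hemi = hemi, region = region,
    stg = region %in% c("A1", "A4", "pINS", "STG+")
  ), class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d vertices (%d per hemisphere, %dx%d grid), %d edges\n",
              x$n, x$n_per_hemi, x$grid["rows"], x$grid["cols"], nrow(x$edges)))
  print(table(x$region[x$hemi == "L"]))
  invisible(x)
}

#' Vertices of a named region
#' @param space a `source_space`.
#' @param region region label(s); `"STG+"` selects only the unlabelled STG+
#'   remainder, `"stg_all"` the full STG+ union.
#' @param hemi optional hemisphere (`"L"` or `"R"`).
#' @return integer vertex ids.
#' @export
region_vertices <- function(space, region, hemi = NULL) {
  sel <- if (identical(region, "stg_all")) space$stg else space$region %in% region
  if (!is.null(hemi)) sel <- sel & space$hemi == hemi
  which(sel)
}
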