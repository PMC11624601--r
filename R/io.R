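#' Export an evoked set, source space and subject table to a directory
#'
#' Layout: `current.dat` (flat little-endian doubles in
#' `[subject, condition, vertex, time]` order, subject fastest),
#' `evoked.json` (shapes, axes, conditions, epoch counts), `space.json`
#' (edges, hemisphere and region labels) and `records.csv`. The same layout is
#' accepted for real exported source estimates by [ingest_real()].
#'
#' @param ev an `evoked_set`.
#' @param space a `source_space`.
#' @param records subject data.frame.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_evoked <- function(ev, space, records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "current.dat"), "wb")
  writeBin(as.vector(ev$current), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(
    shape = dim(ev$current), order = c("subject", "condition", "vertex", "time"),
    conditions = ev$conditions, times = ev$times, fs = ev$fs,
    n_epochs = ev$n_epochs
  ), file.path(dir, "evoked.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    n = space$n, n_per_hemi = space$n_per_hemi, grid = as.list(space$grid),
    edges = space$edges, hemi = space$hemi, region = space$region
  ), file.path(dir, "space.json"), auto_unbox = TRUE, digits = NA)
  write.csv(records, file.path(dir, "records.csv"), row.names = FALSE)
  invisible(dir)
}

#' Ingest an exported evoked-set directory
#'
#' Validates the layout written by [export_evoked()] and reconstructs the
#' evoked set, source space and subject table. Schema violations produce
#' descriptive errors.
#'
#' @param dir directory path.
#' @return list with `evoked`, `space`, `records`.
#' @export
ingest_real <- function(dir) {
  need <- c("current.dat", "evoked.json", "space.json", "records.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) stop("missing file(s) in ", dir, ": ",
                            paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "evoked.json"), simplifyVector = TRUE)
  for (f in c("shape", "conditions", "times", "fs", "n_epochs"))
    if (is.null(meta[[f]])) stop("evoked.json lacks field '", f, "'")
  if (length(meta$shape) != 4L) stop("shape must have 4 entries")
  if (length(meta$conditions) != meta$shape[2])
    stop("conditions (", length(meta$conditions), ") do not match shape[2] (",
         meta$shape[2], ")")
  if (length(meta$times) != meta$shape[4])
    stop("times (", length(meta$times), ") do not match shape[4] (",
         meta$shape[4], ")")
  n_total <- prod(meta$shape)
  con <- file(file.path(dir, "current.dat"), "rb")
  cur <- readBin(con, "double", n_total + 1L, size = 8, endian = "little")
  close(con)
  if (length(cur) != n_total)
    stop("current.dat holds ", length(cur), " doubles, expected ", n_total)
  cur <- array(cur, dim = meta$shape,
               dimnames = list(NULL, meta$conditions, NULL, NULL))
  sp <- jsonlite::read_json(file.path(dir, "space.json"), simplifyVector = TRUE)
  if (length(sp$hemi) != sp$n || length(sp$region) != sp$n)
    stop("space.json labels do not match n = ", sp$n)
  space <- structure(list(
    n = sp$n, n_per_hemi = sp$n_per_hemi,
    grid = unlist(sp$grid), edges = matrix(as.integer(sp$edges), ncol = 2),
    hemi = sp$hemi, region = sp$region,
    stg = sp$region %in% c("A1", "A4", "pINS", "STG+")
  ), class = "source_space")
  records <- utils::read.csv(file.path(dir, "records.csv"))
  if (nrow(records) != meta$shape[1])
    stop("records.csv has ", nrow(records), " rows, expected ", meta$shape[1],
         " subjects")
  n_ep <- matrix(as.numeric(as.matrix(meta$n_epochs)), meta$shape[1],
                 dimnames = list(NULL, meta$conditions))
  evoked <- structure(list(current = cur, times = meta$times, fs = meta$fs,
                           conditions = meta$conditions, n_epochs = n_ep),
                      class = "evoked_set")
  list(evoked = evoked, space = space, records = records)
}
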