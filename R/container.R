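#' Store raw reads in an HDF5 container
#'
#' One group per read under `/reads`, named `read_000001`, `read_000002`, ...
#' Datasets inside each group:
#' \describe{
#'   \item{`signal`}{raw current samples (float64).}
#'   \item{`trace`}{rows x 8 integer matrix, 0-255, columns
#'     A,C,G,T,AA,CC,GG,TT.}
#'   \item{`moves`}{0/1 integer per trace row.}
#'   \item{`ref_name`}{reference transcript id (string).}
#'   \item{`ref_start`, `ref_end`}{0-based half-open alignment interval.}
#'   \item{`truth_rows`}{trace rows per base (simulator ground truth;
#'     absent for real data).}
#'   \item{`modified`, `mod_positions`}{simulator ground truth (optional).}
#' }
#'
#' @param reads list of `raw_read` objects.
#' @param path HDF5 file to create (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_reads_h5 <- function(reads, path) {
  stopifnot(all(vapply(reads, inherits, logical(1), "raw_read")))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "reads")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    g <- sprintf("reads/read_%06d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(rd$signal, path, paste0(g, "/signal"))
    rhdf5::h5write(rd$trace, path, paste0(g, "/trace"))
    rhdf5::h5write(as.integer(rd$moves), path, paste0(g, "/moves"))
    rhdf5::h5write(rd$ref_name, path, paste0(g, "/ref_name"))
    rhdf5::h5write(as.integer(rd$ref_start), path, paste0(g, "/ref_start"))
    rhdf5::h5write(as.integer(rd$ref_end), path, paste0(g, "/ref_end"))
    if (!is.null(rd$truth_rows)) {
      rhdf5::h5write(as.integer(rd$truth_rows), path, paste0(g, "/truth_rows"))
      rhdf5::h5write(as.integer(rd$modified), path, paste0(g, "/modified"))
      rhdf5::h5write(as.integer(rd$mod_positions), path, paste0(g, "/mod_positions"))
    }
  }
  invisible(path)
}

#' @rdname write_reads_h5
#' @return for `read_reads_h5`: the list of `raw_read` objects.
#' @export
read_reads_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ids <- rhdf5::h5ls(path, recursive = 2)
  ids <- sort(ids$name[ids$group == "/reads"])
  lapply(ids, function(id) {
    g <- paste0("reads/", id)
    has <- function(d) {
      tryCatch({rhdf5::h5read(path, paste0(g, "/", d)); TRUE},
               error = function(e) FALSE)
    }
    trace <- rhdf5::h5read(path, paste0(g, "/trace"))
    storage.mode(trace) <- "integer"
    colnames(trace) <- TRACE_CLASSES
    out <- list(
      signal = as.numeric(rhdf5::h5read(path, paste0(g, "/signal"))),
      trace = trace,
      moves = as.integer(rhdf5::h5read(path, paste0(g, "/moves"))),
      ref_name = as.character(rhdf5::h5read(path, paste0(g, "/ref_name"))),
      ref_start = as.integer(rhdf5::h5read(path, paste0(g, "/ref_start"))),
      ref_end = as.integer(rhdf5::h5read(path, paste0(g, "/ref_end"))),
      truth_rows = NULL, modified = NA, mod_positions = NULL)
    if (has("truth_rows")) {
      out$truth_rows <- as.integer(rhdf5::h5read(path, paste0(g, "/truth_rows")))
      out$modified <- as.logical(rhdf5::h5read(path, paste0(g, "/modified")))
      out$mod_positions <- as.integer(rhdf5::h5read(path, paste0(g, "/mod_positions")))
    }
    structure(out, class = "raw_read")
  })
}
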