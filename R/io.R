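# Portable tissue format (JSON, optionally gzipped) and TIFF label-stack
# ingestion.  Adjacency is derived from the stored edges, never stored
# redundantly.

#' Write a tissue sequence to the portable JSON format
#'
#' One JSON object per dataset: `pixel_size_um` and `frames[]`, each frame
#' with `time_s`, `cells[]` (`id`, `polygon` as [[x,y],...], `boundary_cell`)
#' and `edges[]` (`cells` pair, `polyline`).  Paths ending in `.gz` are
#' gzip-compressed.
#'
#' @param seq a `tissue_sequence`.
#' @param path output path (`.json` or `.json.gz`).
#' @return the path, invisibly.
#' @export
write_tissue <- function(seq, path) {
  frames <- lapply(seq$frames, function(fr) {
    list(
      time_s = fr$time,
      cells = lapply(unname(fr$cells), function(cl) list(
        id = cl$id,
        polygon = unname(apply(cl$boundary, 1L, function(r) c(r[1L], r[2L]),
                               simplify = FALSE)),
        boundary_cell = isTRUE(cl$is_boundary_cell)
      )),
      edges = lapply(fr$edges, function(e) list(
        cells = as.integer(e$cells),
        polyline = unname(apply(e$polyline, 1L, function(r) c(r[1L], r[2L]),
                                simplify = FALSE))
      ))
    )
  })
  obj <- list(pixel_size_um = seq$pixel_size, frames = frames)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Read a tissue sequence
#'
#' Reads either the portable JSON format or a TIFF label stack (one 2-D
#' integer page per frame; requires the `tiff` package), in which case every
#' page is polygonised with [polygonize_frame()].
#'
#' @param path input path (`.json`, `.json.gz`, `.tif`, `.tiff`).
#' @param pixel_size pixel size for TIFF input (um).
#' @param frame_interval_s frame interval for TIFF input (s).
#' @param simplify_tol Douglas-Peucker tolerance in pixels for TIFF input.
#' @return a `tissue_sequence`.
#' @export
read_tissue <- function(path, pixel_size = 0.2405, frame_interval_s = 30,
                        simplify_tol = 1) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF stacks requires the 'tiff' package")
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!length(pages)) stop("format error: empty TIFF stack")
    frames <- lapply(seq_along(pages), function(f) {
      polygonize_frame(matrix(as.integer(pages[[f]]), nrow = nrow(pages[[f]])),
                       pixel_size = pixel_size, simplify_tol = simplify_tol,
                       time = (f - 1) * frame_interval_s)
    })
    return(tissue_sequence(frames, pixel_size = pixel_size))
  }
  txt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r"); on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
  if (!length(txt) || !nzchar(paste(txt, collapse = ""))) {
    stop("format error: empty tissue file")
  }
  obj <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                            simplifyVector = FALSE)
  if (is.null(obj$frames)) stop("format error: missing 'frames'")
  frames <- lapply(seq_along(obj$frames), function(f) {
    fr <- obj$frames[[f]]
    if (is.null(fr$time_s)) {
      stop(sprintf("format error in frame %d: missing field 'time_s'", f))
    }
    cells <- lapply(fr$cells, function(cl) {
      if (is.null(cl$id) || is.null(cl$polygon)) {
        stop(sprintf("format error in frame %d: cell missing 'id'/'polygon'", f))
      }
      list(id = as.integer(cl$id),
           boundary = do.call(rbind, lapply(cl$polygon, as.numeric)),
           is_boundary_cell = isTRUE(cl$boundary_cell))
    })
    names(cells) <- vapply(cells, function(cl) as.character(cl$id), character(1))
    edges <- lapply(fr$edges, function(e) {
      if (is.null(e$cells) || is.null(e$polyline)) {
        stop(sprintf("format error in frame %d: edge missing 'cells'/'polyline'", f))
      }
      list(cells = as.integer(unlist(e$cells)),
           polyline = do.call(rbind, lapply(e$polyline, as.numeric)))
    })
    epi_frame(cells, edges, time = as.numeric(fr$time_s))
  })
  tissue_sequence(frames, pixel_size = if (!is.null(obj$pixel_size_um)) {
    obj$pixel_size_um
  } else 0.2405)
}

#' Write a label stack as multi-page TIFF
#'
#' @param stack list of integer label matrices.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_label_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("writing TIFF stacks requires the 'tiff' package")
  }
  # 16-bit encoding
  pages <- lapply(stack, function(M) {
    if (max(M) > 65535L) stop("label too large for 16-bit TIFF")
    M / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label stack written by [write_label_stack()]
#' @param path TIFF path.
#' @return list of integer label matrices.
#' @export
read_label_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF stacks requires the 'tiff' package")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(M) {
    matrix(as.integer(round(M * 65535)), nrow = nrow(M))
  })
}
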