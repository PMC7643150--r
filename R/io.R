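## Landscape and result I/O. Raster snapshots are written as multi-band TIFF
## (bands: stratum code, state-class code, class age, forest-edge flag;
## integer codes stored as value/255 at 8 bits) on an arbitrary local grid
## with 50 m cells (0.25 ha) and no coordinate reference system; the CSV grid
## dump is the plain-text interchange format used by the tests.

#' Export a landscape as a multi-band TIFF
#'
#' Band order: stratum code, state-class code, class age (years), forest-edge
#' flag. Integer values are stored as `value / 255` at 8 bits per sample, so
#' ages up to 255 years round-trip exactly.
#'
#' @param landscape a `bg_landscape`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_tiff <- function(landscape, path) {
  bands <- list(landscape$stratum, landscape$state, landscape$age,
                landscape$forest_edge + 0L)
  if (any(vapply(bands, max, numeric(1)) > 255))
    stop("band value exceeds 8-bit range", call. = FALSE)
  tiff::writeTIFF(lapply(bands, function(b) b / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Import a landscape from a multi-band TIFF
#'
#' Inverse of [write_landscape_tiff()]. The suitability surface is not part
#' of the raster snapshot and comes back `NULL`.
#'
#' @param path file written by [write_landscape_tiff()].
#' @param cell_area cell area in ha.
#' @return A `bg_landscape`.
#' @export
read_landscape_tiff <- function(path, cell_area = 0.25) {
  bands <- tiff::readTIFF(path, all = TRUE)
  if (length(bands) != 4) stop("expected a 4-band landscape TIFF", call. = FALSE)
  dec <- lapply(bands, function(b) matrix(as.integer(round(b * 255)),
                                          nrow(b), ncol(b)))
  strata <- list(stratum = dec[[1]], forest_edge = dec[[4]] == 1L,
                 desert_mask = dec[[1]] %in% c(STRATA[["unsusceptible_desert"]],
                                               STRATA[["susceptible_desert"]]))
  dim(strata$desert_mask) <- dim(dec[[1]])
  new_landscape(strata, state = dec[[2]], age = dec[[3]],
                cell_area = cell_area)
}

#' Dump a landscape to a long-format CSV
#'
#' One row per cell: `row`, `col`, `stratum`, `state`, `age`, `forest_edge`,
#' plus `suitability` when present.
#'
#' @param landscape a `bg_landscape`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  d <- data.frame(row = rep(seq_len(landscape$nrow), landscape$ncol),
                  col = rep(seq_len(landscape$ncol), each = landscape$nrow),
                  stratum = as.vector(landscape$stratum),
                  state = as.vector(landscape$state),
                  age = as.vector(landscape$age),
                  forest_edge = as.integer(landscape$forest_edge))
  if (!is.null(landscape$suitability))
    d$suitability <- as.vector(landscape$suitability)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a landscape from a CSV grid dump
#'
#' @param path file written by [write_landscape_csv()].
#' @param cell_area cell area in ha.
#' @return A `bg_landscape`.
#' @export
read_landscape_csv <- function(path, cell_area = 0.25) {
  d <- utils::read.csv(path)
  nr <- max(d$row); nc <- max(d$col)
  d <- d[order(d$col, d$row), ]
  as_m <- function(v) matrix(v, nr, nc)
  strata <- list(stratum = as_m(as.integer(d$stratum)),
                 forest_edge = as_m(d$forest_edge == 1L),
                 desert_mask = as_m(d$stratum %in%
                                      c(STRATA[["unsusceptible_desert"]],
                                        STRATA[["susceptible_desert"]])))
  suit <- if ("suitability" %in% names(d)) as_m(d$suitability)
  new_landscape(strata, state = as_m(as.integer(d$state)),
                age = as_m(as.integer(d$age)), suitability = suit,
                cell_area = cell_area)
}

#' Write a run's outputs to a directory
#'
#' Writes the tidy result table, per-year fire events, start/end landscape
#' snapshots (TIFF and CSV), a configuration snapshot, and a manifest
#' listing every file with its MD5 checksum. Given the same configuration
#' and master seed, every data file (and hence every checksum) is
#' reproduced byte-identically.
#'
#' @param results a `bg_results` from [run_ensemble()] (or a plain result
#'   data frame).
#' @param out_dir output directory (created if needed).
#' @param config optional configuration list to snapshot.
#' @param landscapes optional named list of `bg_landscape` snapshots (e.g.
#'   `list(start = ..., end = ...)`).
#' @return Data frame manifest (`file`, `md5`), invisibly.
#' @export
write_outputs <- function(results, out_dir, config = NULL, landscapes = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  tab <- if (inherits(results, "bg_results")) results$table else results
  utils::write.csv(tab, file.path(out_dir, "results.csv"), row.names = FALSE)
  if (inherits(results, "bg_results")) {
    ev <- list()
    for (rep in seq_along(results$events)) {
      for (e in results$events[[rep]]) {
        if (is.null(e)) next
        ev[[length(ev) + 1]] <- data.frame(
          realization = rep, year = e$year,
          ignition_row = e$ignition[["row"]], ignition_col = e$ignition[["col"]],
          burned_cells = length(e$burned), burned_area_ha = e$area_ha,
          reached_forest_edge = as.integer(e$reached_forest_edge))
      }
    }
    if (length(ev))
      utils::write.csv(do.call(rbind, ev), file.path(out_dir, "fire_events.csv"),
                       row.names = FALSE)
    if (!is.null(results$fire_summary))
      utils::write.csv(results$fire_summary,
                       file.path(out_dir, "fire_summary.csv"), row.names = FALSE)
  }
  if (!is.null(config)) save_config(config, file.path(out_dir, "config_snapshot.yml"))
  for (nm in names(landscapes)) {
    write_landscape_tiff(landscapes[[nm]],
                         file.path(out_dir, paste0("landscape_", nm, ".tif")))
    write_landscape_csv(landscapes[[nm]],
                        file.path(out_dir, paste0("landscape_", nm, ".csv")))
  }
  files <- setdiff(list.files(out_dir), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
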