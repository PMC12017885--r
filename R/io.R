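# Plain-text interchange: spike rasters as (neuron_id, t_s) CSV,
# connectomes as (pre_id, post_id, kind) edge lists, geometries as
# (id, x[, y]) coordinate tables, synchrony reports as JSON.

#' Write / read a spike raster as CSV
#'
#' Dialect: columns `neuron_id` (1-based) and `t_s` (spike time,
#' seconds); silent neurons are preserved through the `n` argument on
#' read (ids up to `n` with no rows give empty trains).
#'
#' @param raster list of spike-time vectors (s) or an `ingnet_sim`.
#' @param file path.
#' @return `write_raster` returns the path invisibly; `read_raster`
#'   returns a list of spike-time vectors.
#' @export
write_raster <- function(raster, file) {
  if (inherits(raster, "ingnet_sim")) raster <- raster$spikes
  df <- data.frame(neuron_id = rep(seq_along(raster), lengths(raster)),
                   t_s = unlist(raster))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_raster
#' @param n number of neurons (to preserve trailing silent neurons).
#' @export
read_raster <- function(file, n = NULL) {
  df <- read.csv(file)
  if (!all(c("neuron_id", "t_s") %in% names(df)))
    stop("raster CSV must have columns neuron_id, t_s")
  if (is.null(n)) n <- if (nrow(df)) max(df$neuron_id) else 0
  out <- rep(list(numeric(0)), n)
  if (nrow(df)) {
    sp <- split(df$t_s, factor(df$neuron_id, levels = seq_len(n)))
    out <- lapply(sp, function(x) sort(as.numeric(x)))
  }
  unname(out)
}

#' Write / read a connectome as an edge-list CSV
#'
#' Columns `pre_id`, `post_id` (1-based) and `kind` (`chem` or `gj`);
#' gap-junction edges are written once per unordered pair and mirrored
#' on read.
#'
#' @param connectome an `ingnet_connectome`.
#' @param file path.
#' @export
write_connectome <- function(connectome, file) {
  stopifnot(inherits(connectome, "ingnet_connectome"))
  ij <- which(connectome$chem, arr.ind = TRUE)
  df <- data.frame(pre_id = ij[, 1], post_id = ij[, 2],
                   kind = rep("chem", nrow(ij)))
  ij <- which(connectome$gj & upper.tri(connectome$gj), arr.ind = TRUE)
  df <- rbind(df, data.frame(pre_id = ij[, 1], post_id = ij[, 2],
                             kind = rep("gj", nrow(ij))))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_connectome
#' @param geometry the geometry the edge list refers to.
#' @export
read_connectome <- function(file, geometry) {
  df <- read.csv(file)
  n <- geometry$n
  chem <- matrix(FALSE, n, n)
  gjm <- matrix(FALSE, n, n)
  ch <- df[df$kind == "chem", ]
  chem[cbind(ch$pre_id, ch$post_id)] <- TRUE
  gj <- df[df$kind == "gj", ]
  gjm[cbind(gj$pre_id, gj$post_id)] <- TRUE
  gjm <- gjm | t(gjm)
  structure(list(chem = chem, gj = gjm, geometry = geometry),
            class = "ingnet_connectome")
}

#' Write a geometry as CSV
#'
#' @param geometry an `ingnet_geometry`.
#' @param file path.
#' @export
write_geometry <- function(geometry, file) {
  stopifnot(inherits(geometry, "ingnet_geometry"))
  df <- if (geometry$topology == "ring")
    data.frame(id = seq_len(geometry$n), x = geometry$pos)
  else
    data.frame(id = seq_len(geometry$n), x = geometry$pos[, 1],
               y = geometry$pos[, 2])
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a synchrony report as JSON
#'
#' Serializes every scalar field of an `ingnet_synchrony_report` (plus
#' the k(tau) curve) with basic provenance.
#'
#' @param report an `ingnet_synchrony_report`.
#' @param file path.
#' @export
write_report <- function(report, file) {
  stopifnot(inherits(report, "ingnet_synchrony_report"))
  x <- unclass(report)
  x$k_curve <- as.list(x$k_curve)
  x$generated_by <- paste0("ingnet ", as.character(utils::packageVersion("ingnet")))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}
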