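## On-disk artifact formats, all plain text and round-trip faithful:
##   edge list      TSV, two 0-based integer voxel-id columns, i < j, one row
##                  per undirected edge; '#' header carries the voxel universe
##   embedding      CSV voxel_id,r,theta,degree,kappa with '#' header lines
##                  for the model parameters
##   decomposition  CSV voxel_id,coreness
##   profile        JSON {scheme, kmax, core_size, counts{}, fractions{},
##                  pattern}

#' Write / read a brain graph as a TSV edge list
#'
#' @param g a \code{\link{brain_graph}}.
#' @param path output file.
#' @return \code{write_edge_list}: the path, invisibly. \code{read_edge_list}:
#'   the graph.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  el <- matrix(as.integer(el), ncol = 2)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes ", paste(graph_ids(g), collapse = ",")), con)
  if (nrow(el))
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# nodes ")]
  if (!length(hdr)) stop_hc("malformed edge list: missing node header")
  ids <- as.integer(strsplit(sub("^# nodes ", "", hdr[1]), ",")[[1]])
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  edges <- if (length(body)) {
    m <- do.call(rbind, strsplit(body, "\t"))
    if (ncol(m) != 2L) stop_hc("malformed edge list: expected 2 columns")
    matrix(as.integer(m), ncol = 2)
  } else matrix(integer(0), ncol = 2)
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    stop_hc("malformed edge list: self-loop")
  brain_graph(ids, edges)
}

#' Write / read a hyperbolic embedding as CSV
#'
#' Columns \code{voxel_id,r,theta,degree,kappa}; model parameters (beta,
#' R_hat, curvature, loglik) travel in '#' header lines.
#'
#' @param e a \code{hyper_embedding}.
#' @param path output file.
#' @export
write_embedding <- function(e, path) {
  stopifnot(inherits(e, "hyper_embedding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beta %.17g", e$beta), con)
  writeLines(sprintf("# R_hat %.17g", e$R_hat), con)
  writeLines(sprintf("# curvature %.17g", e$curvature), con)
  writeLines(sprintf("# loglik %.17g", e$loglik), con)
  writeLines("voxel_id,r,theta,degree,kappa", con)
  writeLines(sprintf("%d,%.17g,%.17g,%d,%.17g", e$voxel_id, e$r, e$theta,
                     as.integer(e$degree), e$kappa), con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  par <- function(key) {
    h <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (!length(h)) stop_hc("malformed embedding file: missing ", key)
    as.numeric(sub(paste0("^# ", key, " "), "", h[1]))
  }
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  need <- c("voxel_id", "r", "theta", "degree", "kappa")
  if (!identical(names(body), need))
    stop_hc("malformed embedding file: expected header ",
            paste(need, collapse = ","))
  structure(list(voxel_id = as.integer(body$voxel_id), r = body$r,
                 theta = body$theta, kappa = body$kappa,
                 degree = as.numeric(body$degree),
                 beta = par("beta"), R_hat = par("R_hat"),
                 curvature = par("curvature"), loglik = par("loglik"),
                 trace = par("loglik"), n = nrow(body), graph = NULL),
            class = "hyper_embedding")
}

#' Write / read a core decomposition as CSV
#'
#' @param d a \code{core_decomposition}.
#' @param path output file.
#' @export
write_decomposition <- function(d, path) {
  stopifnot(inherits(d, "core_decomposition"))
  utils::write.csv(data.frame(voxel_id = as.integer(names(d$coreness)),
                              coreness = as.integer(d$coreness)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  body <- utils::read.csv(path)
  if (!identical(names(body), c("voxel_id", "coreness")))
    stop_hc("malformed decomposition file")
  core <- stats::setNames(as.integer(body$coreness),
                          as.character(body$voxel_id))
  k_max <- max(core)
  ks <- seq_len(k_max)
  structure(list(coreness = core, k_max = k_max,
                 core_sizes = stats::setNames(
                   vapply(ks, function(k) sum(core >= k), integer(1)),
                   as.character(ks)),
                 kmax_core = as.integer(names(core))[core == k_max],
                 n_components_kmax = NA_integer_),
            class = "core_decomposition")
}

#' Write / read a composition profile as JSON
#'
#' @param p a \code{composition_profile}.
#' @param path output file.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "composition_profile"))
  jsonlite::write_json(
    list(scheme = p$scheme, kmax = p$kmax, core_size = p$core_size,
         counts = p$counts, fractions = p$fractions,
         pattern = if (is.na(p$pattern)) NULL else p$pattern),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$scheme) || is.null(x$counts)) stop_hc("malformed profile JSON")
  structure(list(scheme = x$scheme,
                 counts = lapply(x$counts, as.integer),
                 fractions = lapply(x$fractions, as.numeric),
                 kmax = as.integer(x$kmax), core_size = as.integer(x$core_size),
                 pattern = x$pattern %||% NA_character_),
            class = "composition_profile")
}
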