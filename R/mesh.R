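#' Triangulated surface meshes
#'
#' A `surface_mesh` is a closed triangulated surface standing in for a
#' standardized cortical surface: a list with `vertices` (n x 3 matrix, mm),
#' `faces` (m x 3 integer matrix, 1-based vertex indices), and `labels`
#' (integer parcellation label per vertex, `1..n_regions`). All vertex and
#' face indices are 1-based throughout the package.
#'
#' @name surface_mesh
NULL

#' Build a synthetic cortical surface mesh
#'
#' Constructs a subdivided icosahedron ("icosphere") scaled to roughly the
#' extent of a cortical lobe (20 mm radius, ~40 mm across) and partitions
#' its vertices into `n_regions`
#' contiguous parcels by multi-source breadth-first growth from
#' farthest-point-sampled seed vertices.
#'
#' @param subdivision_level integer >= 1; each level quadruples the faces.
#'   Level n gives `10 * 4^n + 2` vertices.
#' @param n_regions integer >= 2, number of contiguous parcellation regions.
#' @param seed integer RNG seed; the mesh geometry is deterministic, the
#'   parcellation seeds depend on `seed`.
#' @param radius_mm sphere radius in mm (default 20; ~40 mm overall extent).
#' @return a `surface_mesh` object.
#' @export
make_mesh <- function(subdivision_level, n_regions, seed = 1L, radius_mm = 20) {
  if (length(subdivision_level) != 1L || subdivision_level < 1)
    stop("subdivision_level must be a positive integer >= 1")
  if (length(n_regions) != 1L || n_regions < 2)
    stop("n_regions must be >= 2")

  ico <- icosahedron()
  v <- ico$vertices
  f <- ico$faces
  for (i in seq_len(subdivision_level)) {
    s <- subdivide_once(v, f)
    v <- s$vertices
    f <- s$faces
  }
  # project onto the sphere and scale
  v <- v / sqrt(rowSums(v^2)) * radius_mm
  mode(f) <- "integer"
  dimnames(f) <- NULL

  labels <- grow_parcellation(v, f, n_regions, seed)
  structure(list(vertices = v, faces = f, labels = labels,
                 radius_mm = radius_mm),
            class = "surface_mesh")
}

# unit icosahedron: 12 vertices, 20 faces
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# one 4:1 subdivision step; midpoints reprojected to the unit sphere
subdivide_once <- function(v, f) {
  n <- nrow(v)
  a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)                  # undirected edge identity
  uk <- unique(key)
  mid_idx <- match(key, uk) + n         # new-vertex index per half-edge
  first <- !duplicated(key)
  mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  # rows of `mids` follow first appearance, i.e. the order of `uk`
  nf <- nrow(f)
  m12 <- mid_idx[seq_len(nf)]
  m23 <- mid_idx[nf + seq_len(nf)]
  m31 <- mid_idx[2L * nf + seq_len(nf)]
  newf <- rbind(
    cbind(f[, 1], m12, m31),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m31, m23),
    cbind(m12, m23, m31))
  list(vertices = rbind(v, mids), faces = newf)
}

# contiguous parcellation: farthest-point seeds, multi-source BFS on the
# vertex adjacency graph
grow_parcellation <- function(v, f, n_regions, seed) {
  adj <- vertex_adjacency(f, nrow(v))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  seeds <- integer(n_regions)
  seeds[1] <- sample.int(nrow(v), 1L)
  d <- rep(Inf, nrow(v))
  for (k in seq_len(n_regions)) {
    if (k > 1L) seeds[k] <- which.max(d)
    d <- pmin(d, bfs_depth(adj, seeds[k]))
  }
  labels <- integer(nrow(v))
  depth <- rep(Inf, nrow(v))
  frontier <- seeds
  labels[seeds] <- seq_len(n_regions)
  depth[seeds] <- 0
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- integer(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (labels[w] == 0L) {
          labels[w] <- labels[u]
          depth[w] <- lev
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  labels
}

vertex_adjacency <- function(f, n) {
  a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
  el <- unique(rbind(cbind(a, b), cbind(b, a)))
  split(el[, 2], factor(el[, 1], levels = seq_len(n)))
}

bfs_depth <- function(adj, src) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[src] <- 0
  frontier <- src
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- integer(0)
    for (u in frontier) for (w in adj[[u]]) if (is.infinite(d[w])) {
      d[w] <- lev
      nxt <- c(nxt, w)
    }
    frontier <- nxt
  }
  d
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d regions (radius %.1f mm)\n",
              nrow(x$vertices), nrow(x$faces), length(unique(x$labels)),
              x$radius_mm))
  invisible(x)
}

#' Validate a surface mesh
#'
#' Checks closedness-related invariants: every vertex referenced by at least
#' one face, all face indices in range, finite coordinates.
#' @param mesh a `surface_mesh`.
#' @return invisibly `TRUE`; errors with a diagnostic otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  if (min(f) < 1 || max(f) > nrow(v)) stop("face indices out of range")
  ref <- sort(unique(as.vector(f)))
  if (length(ref) != nrow(v))
    stop(sprintf("mesh has %d unreferenced vertices", nrow(v) - length(ref)))
  invisible(TRUE)
}

#' Build the weighted edge graph of a mesh
#'
#' Returns an igraph graph whose edge weights are Euclidean edge lengths in
#' mm; used for geodesic (shortest-path) distances.
#' @param mesh a `surface_mesh`.
#' @return an igraph object with `weight` edge attribute.
#' @export
mesh_graph <- function(mesh) {
  f <- mesh$faces
  a <- c(f[, 1], f[, 2], f[, 3]); b <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(cbind(lo, hi))
  el <- cbind(lo[keep], hi[keep])
  w <- sqrt(rowSums((mesh$vertices[el[, 1], , drop = FALSE] -
                     mesh$vertices[el[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distance matrix between mesh vertices
#'
#' Dijkstra shortest paths over the mesh edge graph. With `from` a subset of
#' vertex indices, returns a `length(from) x n_vertices` matrix.
#' @param mesh a `surface_mesh`.
#' @param from vertex indices (default all).
#' @return matrix of distances in mm.
#' @export
geodesic_distances <- function(mesh, from = NULL) {
  g <- mesh_graph(mesh)
  if (is.null(from)) from <- seq_len(nrow(mesh$vertices))
  igraph::distances(g, v = from, algorithm = "dijkstra")
}

#' Write / read a FreeSurfer binary surface
#'
#' Minimal implementation of the FreeSurfer triangle-surface binary format
#' (big-endian; magic 0xFFFFFE). Parcellation labels travel in a separate
#' TSV via [write_labels()] / [read_labels()].
#' @param mesh a `surface_mesh`.
#' @param path output file.
#' @export
write_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xFF, 0xFF, 0xFE)), con)
  writeChar("created by seegamma\n\n", con, eos = NULL)
  writeBin(as.integer(nrow(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(nrow(mesh$faces)), con, size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

#' @rdname write_surface
#' @param labels optional integer labels to attach (else all 1).
#' @return `read_surface` returns a `surface_mesh` (labels all 1 unless
#'   supplied).
#' @export
read_surface <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("surface file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(255L, 255L, 254L)))
    stop("not a FreeSurfer triangle surface (bad magic)")
  # comment: bytes up to and including "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (length(ch) == 0) stop("malformed surface header")
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  v <- matrix(readBin(con, "numeric", nv * 3, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE)
  f <- matrix(readBin(con, "integer", nf * 3, size = 4, endian = "big"),
              ncol = 3, byrow = TRUE) + 1L
  if (is.null(labels)) labels <- rep(1L, nv)
  m <- structure(list(vertices = v, faces = f, labels = as.integer(labels),
                      radius_mm = NA_real_), class = "surface_mesh")
  validate_mesh(m)
  m
}

#' Write / read per-vertex parcellation labels as TSV
#' @param labels integer vector, one label per vertex.
#' @param path TSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(vertex = seq_along(labels), label = labels),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("vertex", "label") %in% names(d)))
    stop("label TSV must have columns 'vertex' and 'label'")
  as.integer(d$label[order(d$vertex)])
}
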