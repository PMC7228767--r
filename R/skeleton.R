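#' Voxel scale of an SBEM volume
#'
#' Physical size of one voxel along each axis, in nanometres. Anisotropy is
#' the norm for serial block-face EM: the reference dataset used throughout
#' the documentation was imaged at 13.2 x 13.2 x 26 nm.
#'
#' @param sx,sy,sz nm per voxel along x, y, z; all strictly positive
#' @return object of class `voxel_scale` (named numeric length 3)
#' @export
voxel_scale <- function(sx = 13.2, sy = 13.2, sz = 26) {
  s <- c(sx = sx, sy = sy, sz = sz)
  if (!is.numeric(s) || length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
    stopf("voxel scale components must be finite and strictly positive")
  structure(s, class = "voxel_scale")
}

#' Construct a neurite skeleton
#'
#' A skeleton is a tree (or forest, for tracings with gaps) of nodes in voxel
#' coordinates with undirected edges. Node comments carry free text; comments
#' matching the synapse-annotation grammar are parsed separately at forest
#' level (see [parse_annotation()]).
#'
#' @param id unique integer skeleton id
#' @param name skeleton name (usually encodes cell identity/type)
#' @param nodes data.frame with columns `node_id`, `x`, `y`, `z` and optional
#'   `radius`, `comment`
#' @param edges data.frame (or 2-column matrix) with columns `source`,
#'   `target` holding node ids
#' @param soma_node optional node id marking the soma
#' @param validate run structural validation (acyclicity, edge references)
#' @return object of class `skeleton`
#' @export
skeleton <- function(id, name = paste0("skeleton_", id),
                     nodes = data.frame(node_id = integer(), x = numeric(),
                                        y = numeric(), z = numeric()),
                     edges = data.frame(source = integer(), target = integer()),
                     soma_node = NULL, validate = TRUE) {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$radius)) nodes$radius <- NA_real_
  if (is.null(nodes$comment)) nodes$comment <- NA_character_
  edges <- as.data.frame(edges)
  if (ncol(edges) >= 2L) names(edges)[1:2] <- c("source", "target")
  sk <- structure(list(id = as.integer(id), name = as.character(name),
                       nodes = nodes, edges = edges,
                       soma_node = if (is.null(soma_node)) NULL else as.integer(soma_node)),
                  class = "skeleton")
  if (validate) validate_skeleton(sk)
  sk
}

#' Validate skeleton structure
#'
#' Checks node-id uniqueness, that every edge references two existing distinct
#' nodes, and that the edge set is acyclic. Disconnected tracings are legal
#' (manual tracings commonly contain gaps) but are reported with a warning,
#' never silently merged.
#'
#' @param sk a [skeleton()]
#' @param warn_disconnected warn when the skeleton has > 1 connected component
#' @return `sk`, invisibly; the number of components as attribute
#'   `n_components`
#' @export
validate_skeleton <- function(sk, warn_disconnected = TRUE) {
  ids <- sk$nodes$node_id
  if (anyDuplicated(ids))
    stopf("skeleton %d: duplicated node ids: %s", sk$id,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ev <- c(sk$edges$source, sk$edges$target)
  missing <- setdiff(ev, ids)
  if (length(missing))
    stopf("skeleton %d: edges reference missing node ids: %s", sk$id,
          paste(sort(missing), collapse = ", "))
  if (any(sk$edges$source == sk$edges$target))
    stopf("skeleton %d: self-loop edges are not allowed", sk$id)
  ncomp <- length(ids)
  if (nrow(sk$edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sk$edges$source),
                 to = as.character(sk$edges$target)),
      directed = FALSE, vertices = data.frame(name = as.character(ids)))
    if (!igraph::is_forest(g))
      stopf("skeleton %d contains a cycle; skeletons must be trees/forests", sk$id)
    ncomp <- igraph::count_components(g)
  }
  if (!is.null(sk$soma_node) && !(sk$soma_node %in% ids))
    stopf("skeleton %d: soma node %d is not a node", sk$id, sk$soma_node)
  if (warn_disconnected && ncomp > 1L && nrow(sk$nodes) > 1L)
    warnf("skeleton %d ('%s') has %d connected components", sk$id, sk$name, ncomp)
  attr(sk, "n_components") <- ncomp
  invisible(sk)
}

#' Construct a skeleton forest
#'
#' The top-level container: a set of skeletons sharing one voxel scale and
#' optional volume bounds, plus the table of parsed synapse annotations.
#'
#' @param skeletons list of [skeleton()] objects with unique ids
#' @param scale a [voxel_scale()]
#' @param annotations data.frame of parsed annotation records (see
#'   [parse_annotation()]); built automatically by [read_nml()]
#' @param bounds optional voxel box: list(min = c(x,y,z), max = c(x,y,z))
#' @return object of class `skeleton_forest`
#' @export
skeleton_forest <- function(skeletons = list(), scale = voxel_scale(),
                            annotations = empty_annotations(), bounds = NULL) {
  ids <- vapply(skeletons, function(s) s$id, integer(1))
  if (anyDuplicated(ids))
    stopf("duplicated skeleton ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(skeletons) <- as.character(ids)
  f <- structure(list(scale = scale, bounds = bounds, skeletons = skeletons,
                      annotations = annotations),
                 class = "skeleton_forest")
  validate_forest_refs(f)
  f
}

empty_annotations <- function() {
  data.frame(node_id = integer(), skeleton_id = integer(),
             syn_kind = character(), direction = character(),
             partner_type = character(), partner_cell_id = integer(),
             raw_comment = character(), stringsAsFactors = FALSE)
}

validate_forest_refs <- function(f) {
  a <- f$annotations
  if (!nrow(a)) return(invisible(f))
  for (i in seq_len(nrow(a))) {
    sid <- as.character(a$skeleton_id[i])
    sk <- f$skeletons[[sid]]
    if (is.null(sk))
      stopf("annotation %d references missing skeleton %s", i, sid)
    if (!(a$node_id[i] %in% sk$nodes$node_id))
      stopf("annotation %d references missing node %d in skeleton %s",
            i, a$node_id[i], sid)
  }
  invisible(f)
}

#' @export
print.skeleton_forest <- function(x, ...) {
  nn <- sum(vapply(x$skeletons, function(s) nrow(s$nodes), integer(1)))
  cat(sprintf("<skeleton_forest> %d skeletons, %d nodes, %d annotations\n",
              length(x$skeletons), nn, nrow(x$annotations)))
  cat(sprintf("  scale: %g x %g x %g nm/voxel\n",
              x$scale[1], x$scale[2], x$scale[3]))
  invisible(x)
}

#' Convert voxel coordinates to physical nanometres
#'
#' Componentwise product with the voxel scale. Voxel coordinates are 0-based
#' node centres; no half-voxel offset is applied (pass `offset` in voxels to
#' change that convention).
#'
#' @param position numeric length-3 vector or an n x 3 matrix of voxel
#'   coordinates
#' @param scale a [voxel_scale()]
#' @param offset voxel offset added before scaling (default 0)
#' @return positions in nm, same shape as the input
#' @export
to_physical <- function(position, scale, offset = 0) {
  if (is.matrix(position) || is.data.frame(position)) {
    p <- as.matrix(position[, 1:3, drop = FALSE]) + offset
    sweep(p, 2, unclass(scale)[1:3], `*`)
  } else {
    (position + offset) * unclass(scale)[1:3]
  }
}

# n x 3 matrix of a skeleton's node positions in nm, rownames = node ids.
node_phys <- function(sk, scale) {
  m <- to_physical(cbind(sk$nodes$x, sk$nodes$y, sk$nodes$z), scale)
  rownames(m) <- as.character(sk$nodes$node_id)
  m
}

#' Total cable length of a skeleton
#'
#' Sum over edges of the Euclidean distance between physical endpoint
#' positions.
#'
#' @param sk a [skeleton()]
#' @param scale a [voxel_scale()]
#' @return length in micrometres
#' @export
cable_length <- function(sk, scale) {
  if (!nrow(sk$edges)) return(0)
  p <- node_phys(sk, scale)
  a <- p[as.character(sk$edges$source), , drop = FALSE]
  b <- p[as.character(sk$edges$target), , drop = FALSE]
  sum(sqrt(rowSums((a - b)^2))) / 1000
}

# Adjacency list keyed by node id (character), values integer node ids.
adjacency_list <- function(sk) {
  adj <- split(c(sk$edges$target, sk$edges$source),
               as.character(c(sk$edges$source, sk$edges$target)))
  adj
}

#' Geodesic distance along a skeleton
#'
#' Length of the unique tree path between two nodes, computed by a
#' breadth-first parent walk (no external graph library, so tests can use one
#' as an independent oracle).
#'
#' @param sk a [skeleton()]
#' @param a,b node ids
#' @param scale a [voxel_scale()]
#' @return distance in micrometres
#' @export
path_distance <- function(sk, a, b, scale) {
  a <- as.integer(a); b <- as.integer(b)
  if (!(a %in% sk$nodes$node_id) || !(b %in% sk$nodes$node_id))
    stopf("nodes %d and/or %d not in skeleton %d", a, b, sk$id)
  if (a == b) return(0)
  adj <- adjacency_list(sk)
  parent <- new.env(parent = emptyenv())
  assign(as.character(a), NA_integer_, envir = parent)
  frontier <- a
  found <- FALSE
  while (length(frontier) && !found) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[as.character(v)]] %||% integer()) {
        key <- as.character(w)
        if (!exists(key, envir = parent, inherits = FALSE)) {
          assign(key, v, envir = parent)
          if (w == b) { found <- TRUE; break }
          nxt <- c(nxt, w)
        }
      }
      if (found) break
    }
    frontier <- nxt
  }
  if (!found)
    stopf("nodes %d and %d are in different connected components of skeleton %d",
          a, b, sk$id)
  p <- node_phys(sk, scale)
  d <- 0; v <- b
  repeat {
    u <- get(as.character(v), envir = parent)
    if (is.na(u)) break
    d <- d + sqrt(sum((p[as.character(v), ] - p[as.character(u), ])^2))
    v <- u
  }
  d / 1000
}

#' Geodesic distances from one node to all reachable nodes
#'
#' Single-source tree distances by breadth-first traversal; unreachable nodes
#' (other components) are `NA`.
#'
#' @param sk a [skeleton()]
#' @param origin node id
#' @param scale a [voxel_scale()]
#' @return named numeric vector of distances in micrometres (names = node ids)
#' @export
geodesic_from <- function(sk, origin, scale) {
  ids <- sk$nodes$node_id
  p <- node_phys(sk, scale)
  d <- stats::setNames(rep(NA_real_, length(ids)), as.character(ids))
  d[as.character(origin)] <- 0
  if (!nrow(sk$edges)) return(d / 1000)
  adj <- adjacency_list(sk)
  frontier <- as.integer(origin)
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[as.character(v)]] %||% integer()) {
        kw <- as.character(w)
        if (is.na(d[kw])) {
          d[kw] <- d[as.character(v)] +
            sqrt(sum((p[kw, ] - p[as.character(v), ])^2))
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d / 1000
}

#' Export skeletons as SWC files
#'
#' Standard 7-column SWC, one file per skeleton, type column 0 (undefined),
#' physical micrometre coordinates; the root is the soma node when declared.
#'
#' @param forest a [skeleton_forest()]
#' @param dir output directory (created if needed)
#' @return paths of the written files, invisibly
#' @export
write_swc <- function(forest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (sk in forest$skeletons) {
    p <- node_phys(sk, forest$scale) / 1000
    ids <- sk$nodes$node_id
    parent <- rep(-1L, length(ids)); names(parent) <- as.character(ids)
    if (nrow(sk$edges)) {
      adj <- adjacency_list(sk)
      root <- sk$soma_node %||% ids[1]
      visited <- as.character(root)
      frontier <- root
      while (length(frontier)) {
        nxt <- integer()
        for (v in frontier) for (w in adj[[as.character(v)]] %||% integer()) {
          key <- as.character(w)
          if (!(key %in% visited)) {
            visited <- c(visited, key); parent[key] <- v; nxt <- c(nxt, w)
          }
        }
        frontier <- nxt
      }
    }
    rad <- ifelse(is.na(sk$nodes$radius), 1, sk$nodes$radius / 1000)
    lines <- sprintf("%d 0 %s %s %s %s %d", ids,
                     num_fmt(p[, 1]), num_fmt(p[, 2]), num_fmt(p[, 3]),
                     num_fmt(rad), parent[as.character(ids)])
    path <- file.path(dir, sprintf("skeleton_%d.swc", sk$id))
    writeLines(c("# SWC export", lines), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
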