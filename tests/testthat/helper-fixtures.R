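# Shared fixtures: everything is built in code at test time.

# scaled-down generator world: same structure, small n, fast
mini_params <- function(seed = 1, ...) {
  args <- list(n_aii = 2, n_axons = 8, n_rb = 8, n_cb = 2, n_unid = 2,
               n_a17 = 1, n_dac = 3, n_output_synapses = 120,
               ribbons_per_aii_mean = 18, ribbons_per_aii_sd = 2,
               n_dyads = 20, soma_inputs_per_aii = 5,
               branches_per_aii = 4, branch_length_um = 100,
               sac_grid = 8, sac_extent_um = 150, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(synth_params, args)
}

# tiny hand-built skeleton: a path along z with unit-voxel steps
path_skeleton <- function(n = 5, id = 1L, scale = voxel_scale()) {
  skeleton(id, sprintf("path_%d", id),
           nodes = data.frame(node_id = seq_len(n), x = 0, y = 0,
                              z = seq_len(n) - 1),
           edges = data.frame(source = seq_len(n - 1), target = seq_len(n)[-1]))
}

# random tree on n nodes with random voxel positions (random attachment)
random_tree_skeleton <- function(n, id = 1L) {
  parents <- c(NA, vapply(2:n, function(k) sample.int(k - 1, 1), integer(1)))
  skeleton(id, sprintf("tree_%d", id),
           nodes = data.frame(node_id = seq_len(n),
                              x = runif(n, 0, 500), y = runif(n, 0, 500),
                              z = runif(n, 0, 300)),
           edges = data.frame(source = parents[-1], target = 2:n))
}

# axis-aligned frame: OFF plane z = z_off nm, ON plane z = z_on nm
flat_frame <- function(z_off = 10000, z_on = 22000) {
  ipl_frame(plane(c(0, 0, 1), z_off), plane(c(0, 0, 1), z_on),
            orientation_ref = c(0, 0, z_on + 10000))
}

# igraph-based independent oracle for tree geodesics
igraph_path_distance <- function(sk, a, b, scale) {
  p <- to_physical(cbind(sk$nodes$x, sk$nodes$y, sk$nodes$z), scale)
  rownames(p) <- as.character(sk$nodes$node_id)
  w <- sqrt(rowSums((p[as.character(sk$edges$source), , drop = FALSE] -
                       p[as.character(sk$edges$target), , drop = FALSE])^2))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sk$edges$source),
               to = as.character(sk$edges$target), weight = w),
    directed = FALSE,
    vertices = data.frame(name = as.character(sk$nodes$node_id)))
  igraph::distances(g, as.character(a), as.character(b))[1, 1] / 1000
}

# brute-force O(nm) nearest-neighbour oracle (micrometres)
brute_nn <- function(Q, R) {
  vapply(seq_len(nrow(Q)), function(i)
    min(sqrt(rowSums((R - matrix(Q[i, ], nrow(R), 3, byrow = TRUE))^2))),
    numeric(1)) / 1000
}

minimal_nml <- function(path, body) {
  writeLines(c("<?xml version=\"1.0\"?>", "<things>",
               "<parameters><scale x=\"13.2\" y=\"13.2\" z=\"26\"/></parameters>",
               body, "</things>"), path)
  path
}
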